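#' @title Abstract link diagrams and the diagrammatic skein oracle
#'
#' @description
#' A link diagram is encoded combinatorially as a signed Gauss code:
#' one sequence of crossing passages per component, each passage a
#' triple (crossing id, over/under, oriented sign).  This encoding is
#' independent of any geometry, which makes the exhaustive skein
#' recursion on it ([homfly_from_diagram()]) an independent oracle for
#' the geometric pipeline.
#'
#' @name diagram
NULL

#' Extract the signed Gauss code of a link's standard projection
#'
#' Walks the components in order; along each edge passages are ordered
#' by their position on the edge.  Closed and open components are both
#' supported (an open component simply has a non-cyclic passage list).
#'
#' @param link a `polygonal_link` with regular projection.
#' @return a `gauss_code` object: a list with one element per
#'   component, each a data.frame with columns `crossing`, `over`
#'   (logical), `sign`; plus attribute `closed`.
#' @export
gauss_code <- function(link) {
  cr <- find_crossings(link)
  ed <- link_edges(link)
  comps <- vector("list", link_ncomp(link))
  if (nrow(cr) > 0L) {
    # two passages per crossing
    pass <- data.frame(
      crossing = rep(seq_len(nrow(cr)), 2L),
      edge = c(cr$over_edge, cr$under_edge),
      t = c(cr$t_over, cr$t_under),
      over = rep(c(TRUE, FALSE), each = nrow(cr)),
      sign = rep(cr$sign, 2L))
    pass <- pass[order(pass$edge, pass$t), ]
  } else {
    pass <- data.frame(crossing = integer(0), edge = integer(0),
                       t = numeric(0), over = logical(0), sign = integer(0))
  }
  for (k in seq_along(comps)) {
    sel <- pass$edge %in% which(ed[, 3L] == k)
    comps[[k]] <- pass[sel, c("crossing", "over", "sign")]
    rownames(comps[[k]]) <- NULL
  }
  structure(comps, closed = link$closed, class = "gauss_code")
}

#' @export
print.gauss_code <- function(x, ...) {
  cat("<gauss_code>", length(x), "component(s)\n")
  for (k in seq_along(x)) {
    g <- x[[k]]
    cat(sprintf("  [%d]%s ", k,
                if (attr(x, "closed")[k]) "" else " (open)"))
    if (nrow(g) == 0L) cat("-\n")
    else cat(paste0(ifelse(g$over, "O", "U"), g$crossing,
                    ifelse(g$sign > 0, "+", "-"), collapse = " "), "\n")
  }
  invisible(x)
}

#' Build a Gauss code by hand
#'
#' @param ... one integer-matrix or data.frame per component with
#'   columns crossing id, over flag, sign; or a character shorthand
#'   like `"O1+ U2+ O3+ U1+ O2+ U3+"`.
#' @param closed logical per component.
#' @return a `gauss_code` object.
#' @examples
#' # standard diagram of the right-handed trefoil (closed 2-braid)
#' gauss_code_manual("O1+ U2+ O3+ U1+ O2+ U3+")
#' @export
gauss_code_manual <- function(..., closed = TRUE) {
  comps <- lapply(list(...), function(x) {
    if (is.character(x)) {
      toks <- strsplit(trimws(x), "\\s+")[[1]]
      data.frame(
        crossing = as.integer(gsub("^[OU]|[+-]$", "", toks)),
        over = substr(toks, 1L, 1L) == "O",
        sign = ifelse(substr(toks, nchar(toks), nchar(toks)) == "+", 1L, -1L))
    } else {
      x <- as.data.frame(x)
      names(x) <- c("crossing", "over", "sign")
      x$over <- as.logical(x$over)
      x
    }
  })
  structure(comps, closed = rep_len(closed, length(comps)),
            class = "gauss_code")
}

# first passage (component, row) met as an underpass whose partner has
# not been met yet; NULL if the diagram is descending
first_under_passage <- function(g) {
  seen <- integer(0)
  for (k in seq_along(g)) {
    cc <- g[[k]]
    for (r in seq_len(nrow(cc))) {
      id <- cc$crossing[r]
      if (id %in% seen) next
      if (!cc$over[r]) return(list(comp = k, row = r, crossing = id,
                                   sign = cc$sign[r]))
      seen <- c(seen, id)
    }
  }
  NULL
}

gc_switch <- function(g, id) {
  for (k in seq_along(g)) {
    hit <- g[[k]]$crossing == id
    g[[k]]$over[hit] <- !g[[k]]$over[hit]
    g[[k]]$sign[hit] <- -g[[k]]$sign[hit]
  }
  g
}

# oriented smoothing of crossing `id`: reconnect the two strands,
# merging two components into one or splitting one into two
gc_smooth <- function(g, id) {
  locs <- list()
  for (k in seq_along(g)) {
    w <- which(g[[k]]$crossing == id)
    for (r in w) locs[[length(locs) + 1L]] <- c(k, r)
  }
  stopifnot(length(locs) == 2L)
  k1 <- locs[[1]][1]; r1 <- locs[[1]][2]
  k2 <- locs[[2]][1]; r2 <- locs[[2]][2]
  closed <- attr(g, "closed")
  if (k1 == k2) {
    # split: [A x B x] -> [A], [B] (cyclic); for an open component the
    # smoothing of a self-crossing still yields one closed and one open
    # piece: [pre x mid x post] -> closed [mid], open [pre post]
    cc <- g[[k1]]
    lo <- min(r1, r2); hi <- max(r1, r2)
    mid <- cc[setdiff(seq(lo, hi), c(lo, hi)), , drop = FALSE]
    rest <- cc[setdiff(seq_len(nrow(cc)), seq(lo, hi)), , drop = FALSE]
    out <- g[-k1]
    cl <- closed[-k1]
    out <- c(out, list(mid, rest))
    cl <- c(cl, TRUE, closed[k1])
  } else {
    # merge: [A x] + [B x] -> [A B]; only defined when both pieces are
    # closed or the inter-component geometry guarantees consistency
    if (!closed[k1] || !closed[k2])
      stop("oriented smoothing between open components is not defined; ",
           "close the link first")
    c1 <- g[[k1]]; c2 <- g[[k2]]
    # rotate each cyclic word so the smoothed passage sits last, drop it
    rot_drop <- function(cc, r) {
      n <- nrow(cc)
      if (n == 1L) return(cc[0L, , drop = FALSE])
      idx <- ((r + seq_len(n - 1L) - 1L) %% n) + 1L  # r+1, ..., r-1
      cc[idx, , drop = FALSE]
    }
    merged <- rbind(rot_drop(c1, r1), rot_drop(c2, r2))
    out <- g[-c(k1, k2)]
    cl <- closed[-c(k1, k2)]
    out <- c(out, list(merged))
    cl <- c(cl, TRUE)
  }
  structure(out, closed = cl, class = "gauss_code")
}

#' HOMFLY polynomial by exhaustive skein recursion on a diagram
#'
#' Independent oracle: no geometry, no structure reduction.  The
#' recursion systematically locates the first passage (walking
#' components in order) whose crossing is first met as an underpass,
#' and resolves it into the switched and smoothed diagrams.  A diagram
#' with no such passage is descending, hence an unlink whose
#' polynomial is known.  Convention:
#' `l*P(L+) + l^-1*P(L-) + m*P(L0) = 0`, `P(unknot) = 1`.
#'
#' @param g a `gauss_code` (or a `polygonal_link`, converted via
#'   [gauss_code()]).
#' @return a `laurent2` polynomial.
#' @export
homfly_from_diagram <- function(g) {
  if (inherits(g, "polygonal_link")) g <- gauss_code(g)
  stopifnot(inherits(g, "gauss_code"))
  # validate: every crossing id appears exactly twice, once over once under
  ids <- unlist(lapply(g, function(cc) cc$crossing))
  if (length(ids)) {
    tab <- table(ids)
    if (any(tab != 2L)) stop("malformed Gauss code: crossing ids ",
                             paste(names(tab)[tab != 2L], collapse = ", "),
                             " do not appear exactly twice")
    for (id in unique(ids)) {
      ov <- unlist(lapply(g, function(cc) cc$over[cc$crossing == id]))
      if (sum(ov) != 1L) stop("malformed Gauss code: crossing ", id,
                              " needs one over and one under passage")
    }
  }
  rec <- function(g, depth) {
    if (depth > 200L) stop("diagram skein recursion too deep")
    fu <- first_under_passage(g)
    if (is.null(fu)) return(unlink_poly(length(g)))
    eps <- fu$sign
    p_switch <- rec(gc_switch(g, fu$crossing), depth + 1L)
    p_zero <- rec(gc_smooth(g, fu$crossing), depth + 1L)
    skein_combine(eps, p_switch, p_zero)
  }
  rec(g, 0L)
}

# P(L) from the switched and smoothed children:
#   eps = +1 : P = -l^-2 P_switch - l^-1 m P_zero
#   eps = -1 : P = -l^+2 P_switch - l^+1 m P_zero
skein_combine <- function(eps, p_switch, p_zero) {
  stopifnot(eps %in% c(-1L, 1L))
  a <- l2_mono(-1, -2L * eps, 0L)
  b <- l2_mono(-1, -1L * eps, 1L)
  l2_add(l2_mul(a, p_switch), l2_mul(b, p_zero))
}
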