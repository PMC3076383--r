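#' @title Polygonal links, regular projections and crossings
#'
#' @description
#' A polygonal link is an ordered set of 3D points partitioned into
#' components, each component a polygonal path that may be open or
#' closed.  The link must be *simple*: every edge meets only its
#' neighbours, and only at shared endpoints.  All topology in this
#' package is read off the standard projection onto the xy-plane
#' (dropping z), which must be *regular*: finitely many transversal
#' double points, none at a vertex, no two coincident.
#'
#' @name linkcore
NULL

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

link_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Build and validate a polygonal link
#'
#' @param points numeric matrix with 3 columns (x, y, z), one row per
#'   point, in traversal order; units are Angstroms for proteins and
#'   arbitrary otherwise.
#' @param sep integer vector of 1-based start indices of the
#'   components (first element must be 1, strictly increasing).
#' @param closed logical vector, one flag per component; a closed
#'   component has an implicit edge from its last point back to its
#'   first.
#' @param check if `FALSE`, skip the 3D simplicity check (used
#'   internally when the construction guarantees it).
#' @return an object of class `polygonal_link`.
#' @details Open components need at least 2 points and closed ones at
#'   least 3.  Zero-length edges and 3D contacts between non-adjacent
#'   edges are rejected.
#' @export
build_link <- function(points, sep = 1L, closed = TRUE, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  if (anyNA(points) || any(!is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  sep <- as.integer(sep)
  if (length(sep) < 1L || sep[1] != 1L || is.unsorted(sep, strictly = TRUE) ||
      any(sep > n))
    stop("sep must be strictly increasing 1-based start indices beginning at 1")
  nc <- length(sep)
  closed <- rep_len(as.logical(closed), nc)
  ends <- c(sep[-1] - 1L, n)
  sizes <- ends - sep + 1L
  if (any(sizes < 2L)) stop("every component needs at least 2 points")
  if (any(closed & sizes < 3L)) stop("closed components need at least 3 points")
  link <- structure(list(points = points, sep = sep, closed = closed),
                    class = "polygonal_link")
  ed <- link_edges(link)
  len <- sqrt(rowSums((points[ed[, 2L], , drop = FALSE] -
                       points[ed[, 1L], , drop = FALSE])^2))
  dg <- bbox_diag(points)
  if (any(len <= 1e-12 * max(dg, 1)))
    stop("degenerate (zero-length) edge at edge id ",
         paste(which(len <= 1e-12 * max(dg, 1)), collapse = ", "))
  if (check) {
    bad <- nonsimple_pairs(link)
    if (nrow(bad) > 0L)
      link_error(sprintf("link is not simple: edges %d and %d intersect in 3D",
                         bad[1, 1], bad[1, 2]), "skeinpath_nonsimple")
  }
  link
}

#' @export
print.polygonal_link <- function(x, ...) {
  nc <- length(x$sep)
  cat(sprintf("<polygonal_link> %d point(s), %d component(s) [%s]\n",
              nrow(x$points), nc,
              paste(ifelse(x$closed, "closed", "open"), collapse = ", ")))
  invisible(x)
}

bbox_diag <- function(points) {
  rng <- apply(points, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

link_ncomp <- function(link) length(link$sep)

comp_of_point <- function(link, idx) {
  findInterval(idx, link$sep)
}

comp_points <- function(link, k) {
  ends <- c(link$sep[-1] - 1L, nrow(link$points))
  seq.int(link$sep[k], ends[k])
}

#' Edge table of a link
#'
#' @param link a `polygonal_link`.
#' @return integer matrix with columns `from`, `to`, `comp`; one row per
#'   oriented edge, in traversal order (closing edge of a closed
#'   component last within the component).
#' @export
link_edges <- function(link) {
  nc <- length(link$sep)
  out <- vector("list", nc)
  for (k in seq_len(nc)) {
    idx <- comp_points(link, k)
    m <- length(idx)
    from <- idx[-m]; to <- idx[-1]
    if (link$closed[k]) { from <- c(from, idx[m]); to <- c(to, idx[1]) }
    out[[k]] <- cbind(from = from, to = to, comp = k)
  }
  do.call(rbind, out)
}

# adjacency: edges sharing a point index
edges_adjacent <- function(ed, i, j) {
  ed[i, 1L] == ed[j, 1L] || ed[i, 1L] == ed[j, 2L] ||
    ed[i, 2L] == ed[j, 1L] || ed[i, 2L] == ed[j, 2L]
}

# all non-adjacent edge id pairs (i < j), as a 2-column matrix
nonadjacent_pairs <- function(link, ed = link_edges(link)) {
  ne <- nrow(ed)
  if (ne < 2L) return(matrix(integer(0), 0L, 2L))
  idx <- which(upper.tri(matrix(0, ne, ne)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  adj <- ed[i, 1L] == ed[j, 1L] | ed[i, 1L] == ed[j, 2L] |
         ed[i, 2L] == ed[j, 1L] | ed[i, 2L] == ed[j, 2L]
  cbind(i[!adj], j[!adj])
}

# minimal distance between segment pairs (vectorized rows);
# standard clamped closest-point computation
seg_dist3 <- function(P1, P2, Q1, Q2) {
  d1 <- P2 - P1; d2 <- Q2 - Q1; r <- P1 - Q1
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2); f <- rowSums(d2 * r)
  b <- rowSums(d1 * d2); c <- rowSums(d1 * r)
  denom <- a * e - b * b
  s <- ifelse(denom > 1e-30, pmin(pmax((b * f - c * e) / denom, 0), 1), 0)
  t <- (b * s + f) / pmax(e, 1e-300)
  tcl <- pmin(pmax(t, 0), 1)
  s2 <- pmin(pmax((b * tcl - c) / pmax(a, 1e-300), 0), 1)
  cp1 <- P1 + d1 * s2
  cp2 <- Q1 + d2 * tcl
  sqrt(rowSums((cp1 - cp2)^2))
}

# non-adjacent edge pairs that come closer than tolerance in 3D
nonsimple_pairs <- function(link, tol = NULL) {
  ed <- link_edges(link)
  prs <- nonadjacent_pairs(link, ed)
  if (nrow(prs) == 0L) return(matrix(integer(0), 0L, 2L))
  if (is.null(tol)) tol <- 1e-9 * max(bbox_diag(link$points), 1)
  P <- link$points
  d <- seg_dist3(P[ed[prs[, 1L], 1L], , drop = FALSE],
                 P[ed[prs[, 1L], 2L], , drop = FALSE],
                 P[ed[prs[, 2L], 1L], , drop = FALSE],
                 P[ed[prs[, 2L], 2L], , drop = FALSE])
  prs[d <= tol, , drop = FALSE]
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# all projection crossing data; used by both find_crossings and the
# regularity test.  Returns list(cross = data.frame, regular, reason).
projection_scan <- function(link) {
  ed <- link_edges(link)
  P <- link$points
  dg <- max(bbox_diag(P), 1e-12)
  tol_reg <- 1e-7 * dg            # closeness that voids regularity
  prs <- nonadjacent_pairs(link, ed)
  empty <- data.frame(e1 = integer(0), e2 = integer(0), t1 = numeric(0),
                      t2 = numeric(0), over1 = logical(0), sign = integer(0),
                      x = numeric(0), y = numeric(0))
  if (nrow(prs) == 0L)
    return(list(cross = empty, regular = TRUE, reason = NULL))
  i <- prs[, 1L]; j <- prs[, 2L]
  p1 <- P[ed[i, 1L], , drop = FALSE]; p2 <- P[ed[i, 2L], , drop = FALSE]
  q1 <- P[ed[j, 1L], , drop = FALSE]; q2 <- P[ed[j, 2L], , drop = FALSE]
  rx <- p2[, 1L] - p1[, 1L]; ry <- p2[, 2L] - p1[, 2L]
  sx <- q2[, 1L] - q1[, 1L]; sy <- q2[, 2L] - q1[, 2L]
  qpx <- q1[, 1L] - p1[, 1L]; qpy <- q1[, 2L] - p1[, 2L]
  den <- cross2(rx, ry, sx, sy)
  lr <- sqrt(rx^2 + ry^2); ls <- sqrt(sx^2 + sy^2)
  par <- abs(den) <= 1e-12 * lr * ls
  # parallel overlap in projection?
  if (any(par)) {
    off <- abs(cross2(qpx, qpy, rx, ry)) / pmax(lr, 1e-300)
    t0 <- (qpx * rx + qpy * ry) / pmax(lr^2, 1e-300)
    t1p <- t0 + (sx * rx + sy * ry) / pmax(lr^2, 1e-300)
    overlap <- par & off < tol_reg &
      pmin(pmax(t0, t1p), 1) - pmax(pmin(t0, t1p), 0) > -1e-12
    if (any(overlap))
      return(list(cross = empty, regular = FALSE,
                  reason = "parallel overlapping edges in projection"))
  }
  t <- ifelse(par, NA_real_, cross2(qpx, qpy, sx, sy) / den)
  u <- ifelse(par, NA_real_, cross2(qpx, qpy, rx, ry) / den)
  hit <- !par & t > 0 & t < 1 & u > 0 & u < 1
  # near-vertex transversal passes void regularity
  near_vertex <- !par &
    ((t > -tol_reg / lr & t < 1 + tol_reg / lr &
      u > -tol_reg / ls & u < 1 + tol_reg / ls) &
     (pmin(t, 1 - t) * lr < tol_reg | pmin(u, 1 - u) * ls < tol_reg))
  if (any(near_vertex, na.rm = TRUE))
    return(list(cross = empty, regular = FALSE,
                reason = "crossing too close to a vertex"))
  if (!any(hit)) return(list(cross = empty, regular = TRUE, reason = NULL))
  hi <- which(hit)
  cx <- p1[hi, 1L] + t[hi] * rx[hi]
  cy <- p1[hi, 2L] + t[hi] * ry[hi]
  # distinct crossings must be separated
  if (length(hi) > 1L) {
    dmin <- min(dist(cbind(cx, cy)))
    if (dmin < tol_reg)
      return(list(cross = empty, regular = FALSE,
                  reason = "two crossings (or a triple point) coincide"))
  }
  z1 <- p1[hi, 3L] + t[hi] * (p2[hi, 3L] - p1[hi, 3L])
  z2 <- q1[hi, 3L] + u[hi] * (q2[hi, 3L] - q1[hi, 3L])
  over1 <- z1 > z2
  # oriented sign, right-hand convention: approach along the underpass;
  # overpass running left-to-right is +1
  dox <- ifelse(over1, rx[hi], sx[hi]); doy <- ifelse(over1, ry[hi], sy[hi])
  dux <- ifelse(over1, sx[hi], rx[hi]); duy <- ifelse(over1, sy[hi], ry[hi])
  sgn <- ifelse(cross2(dox, doy, dux, duy) > 0, 1L, -1L)
  cr <- data.frame(e1 = i[hi], e2 = j[hi], t1 = t[hi], t2 = u[hi],
                   over1 = over1, sign = sgn, x = cx, y = cy)
  list(cross = cr, regular = TRUE, reason = NULL)
}

#' Is the standard projection of a link regular?
#'
#' @param link a `polygonal_link`.
#' @return `TRUE`/`FALSE` with attribute `reason` when irregular.
#' @export
is_regular <- function(link) {
  sc <- projection_scan(link)
  if (!sc$regular) return(structure(FALSE, reason = sc$reason))
  TRUE
}

#' Crossings of the standard projection
#'
#' Every pair of non-adjacent edges whose xy-projections intersect
#' transversally yields one crossing record.  Over/under comes from the
#' z coordinates of the two lifted points; the oriented sign follows
#' the right-hand convention (approach along the underpass in the
#' orientation direction; overpass running left to right is +1).
#'
#' @param link a `polygonal_link` whose projection is regular.
#' @return a data.frame with one row per crossing and columns
#'   `over_edge`, `under_edge`, `t_over`, `t_under` (position of the
#'   crossing along each edge, in (0,1)), `sign`, `x`, `y`.
#' @export
find_crossings <- function(link) {
  sc <- projection_scan(link)
  if (!sc$regular)
    link_error(paste0("non-regular projection (", sc$reason,
                      "); apply ensure_general_position first"),
               "skeinpath_nonregular")
  cr <- sc$cross
  data.frame(over_edge  = ifelse(cr$over1, cr$e1, cr$e2),
             under_edge = ifelse(cr$over1, cr$e2, cr$e1),
             t_over     = ifelse(cr$over1, cr$t1, cr$t2),
             t_under    = ifelse(cr$over1, cr$t2, cr$t1),
             sign = cr$sign, x = cr$x, y = cr$y)
}

random_rotation <- function() {
  # uniform rotation from a random unit quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

rotate_link <- function(link, R) {
  out <- link
  out$points <- link$points %*% t(R)
  out
}

#' Rotate a link into general position
#'
#' Returns the link unchanged if its standard projection is already
#' regular; otherwise applies rigid rotations drawn deterministically
#' from `seed` until the projection becomes regular.
#'
#' @param link a simple `polygonal_link`.
#' @param seed integer seed controlling the rotation sequence.
#' @param max_attempts number of rotations to try before giving up.
#' @return a `polygonal_link` with a regular standard projection.
#' @export
ensure_general_position <- function(link, seed = 1L, max_attempts = 50L) {
  if (isTRUE(is_regular(link))) return(link)
  with_seed(seed, {
    for (k in seq_len(max_attempts)) {
      cand <- rotate_link(link, random_rotation())
      if (isTRUE(is_regular(cand))) return(cand)
    }
    link_error(sprintf(
      "no regular projection found after %d rotations: coincident geometry?",
      max_attempts), "skeinpath_degenerate")
  })
}

#' Mirror image of a link
#'
#' Reflects through the xy-plane (negates z).  Every crossing of the
#' standard projection keeps its position but swaps over/under and
#' negates its oriented sign.
#'
#' @param link a `polygonal_link`.
#' @return the z-negated copy.
#' @export
mirror_link <- function(link) {
  out <- link
  out$points[, 3L] <- -out$points[, 3L]
  out
}

#' Reverse the orientation of components
#'
#' @param link a `polygonal_link`.
#' @param comps component ids to reverse (default: all).
#' @return the link with the selected components' point order reversed.
#' @export
reverse_link <- function(link, comps = seq_along(link$sep)) {
  out <- link
  for (k in comps) {
    idx <- comp_points(link, k)
    out$points[idx, ] <- link$points[rev(idx), ]
  }
  out
}

#' Signed intersection matrix of two edge sets
#'
#' Entry (i, j) is +1 when the projections of edges `E[i]` and `F[j]`
#' cross with `E[i]` passing over, -1 when it passes under, and 0 when
#' the projections do not cross.  With `E == F` the matrix is
#' antisymmetric with zero diagonal.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param E,F integer vectors of edge ids (default: all edges).
#' @return an integer matrix of dimension `length(E) x length(F)` with
#'   `dimnames` the edge ids.
#' @export
intersection_matrix <- function(link, E = NULL, F = NULL) {
  ne <- nrow(link_edges(link))
  if (is.null(E)) E <- seq_len(ne)
  if (is.null(F)) F <- seq_len(ne)
  cr <- find_crossings(link)
  M <- matrix(0L, length(E), length(F), dimnames = list(E, F))
  if (nrow(cr) > 0L) {
    ei <- match(cr$over_edge, E); fj <- match(cr$under_edge, F)
    ok <- !is.na(ei) & !is.na(fj)
    M[cbind(ei[ok], fj[ok])] <- 1L
    ei <- match(cr$under_edge, E); fj <- match(cr$over_edge, F)
    ok <- !is.na(ei) & !is.na(fj)
    M[cbind(ei[ok], fj[ok])] <- -1L
  }
  M
}

#' Read and write plain-text coordinate files
#'
#' One `x y z` triple per line; a blank line separates components; each
#' component is preceded by a header line `# closed` or `# open`.
#' Round-trips coordinates to 12 significant digits.
#'
#' @param link a `polygonal_link`.
#' @param path file path.
#' @return `read_link_file` returns a `polygonal_link`;
#'   `write_link_file` returns `path` invisibly.
#' @export
write_link_file <- function(link, path) {
  con <- file(path, "w"); on.exit(close(con))
  nc <- length(link$sep)
  for (k in seq_len(nc)) {
    writeLines(if (link$closed[k]) "# closed" else "# open", con)
    idx <- comp_points(link, k)
    writeLines(apply(link$points[idx, , drop = FALSE], 1L,
                     function(p) paste(formatC(p, digits = 12, format = "g"),
                                       collapse = " ")), con)
    if (k < nc) writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_link_file
#' @export
read_link_file <- function(path) {
  lines <- readLines(path)
  pts <- list(); sep <- integer(0); closed <- logical(0)
  cur <- list(); cur_closed <- NA; n_seen <- 0L
  flush_comp <- function() {
    if (length(cur) == 0L) return()
    sep <<- c(sep, n_seen + 1L)
    closed <<- c(closed, isTRUE(cur_closed))
    pts[[length(pts) + 1L]] <<- do.call(rbind, cur)
    n_seen <<- n_seen + length(cur)
    cur <<- list(); cur_closed <<- NA
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "") { flush_comp(); next }
    if (startsWith(t, "#")) {
      tag <- trimws(sub("^#", "", t))
      if (tag == "closed") cur_closed <- TRUE
      else if (tag == "open") cur_closed <- FALSE
      next
    }
    v <- as.numeric(strsplit(t, "\\s+")[[1]])
    if (length(v) != 3L || anyNA(v))
      stop("malformed coordinate line: ", ln)
    cur[[length(cur) + 1L]] <- v
  }
  flush_comp()
  if (length(pts) == 0L) stop("no coordinates in file ", path)
  build_link(do.call(rbind, pts), sep, closed)
}
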