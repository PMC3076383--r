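#' @title Minimal Structure Reduction (MSR)
#'
#' @description
#' MSR iterates the Generalized Reidemeister Move (GRM): the
#' replacement of a subpath M by the straight segment joining its
#' endpoints, admissible only when the move provably preserves the
#' ambient isotopy class.  Admissibility is decided from the signed
#' intersection matrix of the standard projection:
#'
#' * C1 (triviality): M is ascending or descending — at every
#'   self-crossing of M the strand met first passes consistently over
#'   or consistently under;
#' * C2 (separability): the over/under statuses of crossings between M
#'   and the other components form a set with at most one element;
#' * C3 (concordance): the union of that set with the statuses of M
#'   against the remainder of its own component still has at most one
#'   element.
#'
#' In addition the replacement segment itself must share that single
#' status against everything it crosses, must keep the link simple in
#' 3D, and must leave the projection regular.  Under these conditions
#' the subpath can be lifted entirely above (or pushed entirely below)
#' the rest of the link, straightened, and dropped onto the segment —
#' an explicit ambient isotopy.
#'
#' Unlike elementary-deformation schemes that delete one vertex per
#' step, a single GRM may remove an arbitrarily long subpath; the move
#' length `i_f - i_s - 2` is 0 exactly for the classical one-vertex
#' triangle move.
#'
#' @name msr
NULL

# local edge bookkeeping -----------------------------------------------

comp_meta <- function(link) {
  nc <- length(link$sep)
  n <- nrow(link$points)
  ends <- c(link$sep[-1] - 1L, n)
  sizes <- ends - link$sep + 1L
  ecount <- sizes - 1L + as.integer(link$closed)
  list(start = link$sep, end = ends, size = sizes,
       ecount = ecount, eoff = cumsum(c(0L, ecount[-nc])))
}

# edge ids of the subpath [i_s, i_f] (global point indices, non-wrapping)
subpath_edges <- function(link, comp, i_s, i_f) {
  cm <- comp_meta(link)
  ls <- i_s - cm$start[comp] + 1L
  lf <- i_f - cm$start[comp] + 1L
  cm$eoff[comp] + seq(ls, lf - 1L)
}

#' GRM admissibility conditions from the intersection matrix
#'
#' Pure predicate: evaluates C1 (triviality of the subpath), C2
#' (separability from the other components) and C3 (concordance with
#' the remainder of its own component) for a move candidate, using
#' only the signed intersection matrix.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param matrix its full signed intersection matrix
#'   ([intersection_matrix()]).
#' @param candidate list with `comp`, `i_s`, `i_f` (global point
#'   indices, `i_f >= i_s + 2`, within one component, non-wrapping).
#' @return list `ok` (logical) and `which_failed` (`"C1"`, `"C2"`,
#'   `"C3"` or `NA`).
#' @export
grm_conditions <- function(link, matrix, candidate) {
  comp <- candidate$comp; i_s <- candidate$i_s; i_f <- candidate$i_f
  me <- subpath_edges(link, comp, i_s, i_f)
  ed <- link_edges(link)
  all_e <- seq_len(nrow(ed))
  own <- setdiff(which(ed[, 3L] == comp), me)
  other <- which(ed[, 3L] != comp)
  # C1: statuses at self-crossings of M, read on the first-met edge
  sub <- matrix[me, me, drop = FALSE]
  self_status <- sub[upper.tri(sub)]
  self_status <- self_status[self_status != 0L]
  if (length(unique(self_status)) > 1L)
    return(list(ok = FALSE, which_failed = "C1"))
  s_other <- matrix[me, other, drop = FALSE]
  s_other <- unique(s_other[s_other != 0L])
  if (length(s_other) > 1L)
    return(list(ok = FALSE, which_failed = "C2"))
  s_own <- matrix[me, own, drop = FALSE]
  s_own <- unique(s_own[s_own != 0L])
  if (length(unique(c(s_other, s_own))) > 1L)
    return(list(ok = FALSE, which_failed = "C3"))
  list(ok = TRUE, which_failed = NA_character_)
}

# crossings/status of a candidate segment (a -> b) against the kept
# edges; returns NULL when the configuration is inadmissible
# (non-simple in 3D, irregular projection), otherwise a list with the
# kept edge ids crossed and the over/under status of the segment
segment_scan <- function(link, ed, keep, a, b, adj, tol3, tolreg) {
  P <- link$points
  A <- P[a, ]; B <- P[b, ]
  v <- B - A
  if (sqrt(sum(v^2)) <= tol3) return(NULL)
  ke <- setdiff(keep, adj)
  if (length(ke) == 0L)
    return(list(edges = integer(0), over = logical(0)))
  P1 <- P[ed[ke, 1L], , drop = FALSE]; P2 <- P[ed[ke, 2L], , drop = FALSE]
  n <- length(ke)
  Am <- matrix(A, n, 3L, byrow = TRUE); Bm <- matrix(B, n, 3L, byrow = TRUE)
  if (any(seg_dist3(Am, Bm, P1, P2) <= tol3)) return(NULL)
  # fold-back against the adjacent edges (projection overlap)
  for (ae in adj) {
    w <- P[ed[ae, 2L], 1:2] - P[ed[ae, 1L], 1:2]
    cr <- cross2(v[1], v[2], w[1], w[2])
    if (abs(cr) <= 1e-12 * sqrt(sum(v[1:2]^2)) * sqrt(sum(w^2)) &&
        sum(v[1:2] * w) < 0) return(NULL)
  }
  rx <- v[1]; ry <- v[2]
  sx <- P2[, 1L] - P1[, 1L]; sy <- P2[, 2L] - P1[, 2L]
  qpx <- P1[, 1L] - A[1]; qpy <- P1[, 2L] - A[2]
  den <- cross2(rx, ry, sx, sy)
  lr <- sqrt(rx^2 + ry^2); ls <- sqrt(sx^2 + sy^2)
  par <- abs(den) <= 1e-12 * lr * ls
  if (any(par)) {
    off <- abs(cross2(qpx[par], qpy[par], rx, ry)) / lr
    t0 <- (qpx[par] * rx + qpy[par] * ry) / lr^2
    t1p <- t0 + (sx[par] * rx + sy[par] * ry) / lr^2
    bad <- off < tolreg &
      pmin(pmax(t0, t1p), 1) - pmax(pmin(t0, t1p), 0) > -1e-12
    if (any(bad)) return(NULL)
  }
  t <- ifelse(par, NA_real_, cross2(qpx, qpy, sx, sy) / den)
  u <- ifelse(par, NA_real_, cross2(qpx, qpy, rx, ry) / den)
  near <- !par &
    (t > -tolreg / lr & t < 1 + tolreg / lr &
     u > -tolreg / ls & u < 1 + tolreg / ls) &
    (pmin(t, 1 - t) * lr < tolreg | pmin(u, 1 - u) * ls < tolreg)
  if (any(near, na.rm = TRUE)) return(NULL)
  hit <- which(!par & t > 0 & t < 1 & u > 0 & u < 1)
  if (length(hit) > 1L) {
    cx <- A[1] + t[hit] * rx; cy <- A[2] + t[hit] * ry
    if (min(dist(cbind(cx, cy))) < tolreg) return(NULL)
  }
  zs <- A[3] + t[hit] * v[3]
  ze <- P1[hit, 3L] + u[hit] * (P2[hit, 3L] - P1[hit, 3L])
  list(edges = ke[hit], over = zs > ze)
}

#' Attempt one Generalized Reidemeister Move
#'
#' Tries candidates starting at `start_index`, longest first (largest
#' end index shrinking towards `start_index + 2`), and commits the
#' first admissible one.  On acceptance the intersection matrix is
#' updated incrementally: rows/columns of the removed edges are
#' deleted and one freshly computed row/column is inserted for the new
#' edge — never a full recomputation.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param matrix current full intersection matrix, consistent with
#'   `link`.
#' @param start_index global point index at which candidate subpaths
#'   start.
#' @return list `link`, `matrix`, `accepted`, `move` (the move as
#'   `list(comp, i_s, i_f, length)` or `NULL`).
#' @export
grm <- function(link, matrix, start_index) {
  ed <- link_edges(link)
  if (nrow(ed) != nrow(matrix) || nrow(ed) != ncol(matrix))
    stop("internal error: matrix inconsistent with link")
  cm <- comp_meta(link)
  comp <- comp_of_point(link, start_index)
  c0 <- cm$start[comp]; c1 <- cm$end[comp]; nk <- cm$size[comp]
  i_s <- start_index
  max_if <- if (link$closed[comp]) min(c1, i_s + nk - 2L) else c1
  if (max_if < i_s + 2L)
    return(list(link = link, matrix = matrix, accepted = FALSE, move = NULL))
  dg <- max(bbox_diag(link$points), 1e-12)
  tol3 <- 1e-9 * dg; tolreg <- 1e-7 * dg
  for (i_f in seq(max_if, i_s + 2L)) {
    cand <- list(comp = comp, i_s = i_s, i_f = i_f)
    cc <- grm_conditions(link, matrix, cand)
    if (!cc$ok) next
    me <- subpath_edges(link, comp, i_s, i_f)
    keep <- setdiff(seq_len(nrow(ed)), me)
    # adjacent edges of the replacement segment: arriving at i_s,
    # leaving i_f (the closing edge when i_s is the component head)
    adj <- integer(0)
    ls <- i_s - c0 + 1L; lf <- i_f - c0 + 1L
    if (ls > 1L) adj <- c(adj, cm$eoff[comp] + ls - 1L)
    else if (link$closed[comp]) adj <- c(adj, cm$eoff[comp] + nk)
    if (lf <= nk - 1L) adj <- c(adj, cm$eoff[comp] + lf)
    else if (link$closed[comp]) adj <- c(adj, cm$eoff[comp] + nk)
    adj <- unique(adj)
    sc <- segment_scan(link, ed, keep, i_s, i_f, adj, tol3, tolreg)
    if (is.null(sc)) next
    # shared-status condition including the replacement segment
    m_status <- matrix[me, keep, drop = FALSE]
    m_status <- unique(m_status[m_status != 0L])
    s_status <- unique(ifelse(sc$over, 1L, -1L))
    if (length(unique(c(m_status, s_status))) > 1L) next
    # commit
    return(commit_grm(link, matrix, ed, cm, cand, me, keep, sc))
  }
  list(link = link, matrix = matrix, accepted = FALSE, move = NULL)
}

commit_grm <- function(link, matrix, ed, cm, cand, me, keep, sc) {
  comp <- cand$comp; i_s <- cand$i_s; i_f <- cand$i_f
  drop_pts <- seq(i_s + 1L, i_f - 1L)
  new_points <- link$points[-drop_pts, , drop = FALSE]
  ndrop <- length(drop_pts)
  new_sep <- link$sep - ifelse(link$sep > i_f, ndrop, 0L)
  link2 <- structure(list(points = new_points, sep = as.integer(new_sep),
                          closed = link$closed), class = "polygonal_link")
  # incremental matrix: delete removed rows/cols, insert the new edge's
  # row/col at the position the removed block occupied
  kept_M <- matrix[keep, keep, drop = FALSE]
  pos <- sum(keep < me[1L]) + 1L       # new edge's index among new edges
  nk2 <- length(keep)
  newrow <- integer(nk2)
  if (length(sc$edges))
    newrow[match(sc$edges, keep)] <- ifelse(sc$over, 1L, -1L)
  M2 <- matrix(0L, nk2 + 1L, nk2 + 1L)
  old_pos <- seq_len(nk2)
  new_pos <- old_pos + (old_pos >= pos)
  M2[new_pos, new_pos] <- kept_M
  M2[pos, -pos] <- newrow
  M2[-pos, pos] <- -newrow
  list(link = link2, matrix = M2, accepted = TRUE,
       move = list(comp = comp, i_s = i_s, i_f = i_f,
                   length = i_f - i_s - 2L))
}

# relabel a closed component so its stored seam moves by `shift`
reroot_component <- function(link, k, shift) {
  if (!link$closed[k]) return(link)
  idx <- comp_points(link, k)
  n <- length(idx)
  shift <- ((shift %% n) + n) %% n
  if (shift == 0L) return(link)
  link$points[idx, ] <- link$points[idx[c((shift + 1L):n, 1L:shift)], ]
  link
}

#' Reduce a link to (an approximation of) its minimal structure
#'
#' Sweeps start indices in order, applying [grm()]; an accepted move
#' restarts the sweep at the same index.  When a full sweep accepts no
#' move, closed components are relabelled at a shifted seam and the
#' sweep retried, so that subpaths spanning the stored seam are also
#' considered; when nothing is accepted in any relabelling the
#' structure is minimal.  Every accepted move preserves the ambient
#' isotopy class, so the invariants of the reduced link equal those of
#' the input.
#'
#' @param link a simple `polygonal_link` (general position is ensured
#'   automatically).
#' @param iteration_limit maximum number of sweeps (default
#'   `10 * n_points`, effectively until fixpoint); `0` returns the
#'   input unchanged.
#' @param seed seed for [ensure_general_position()].
#' @return list `link` (reduced), `trace` (data.frame with columns
#'   `step`, `residual_points`, `move_length`, `component`, `i_s`,
#'   `i_f`), `complete` (`FALSE` when the iteration limit cut the
#'   reduction short).
#' @export
msr_reduce <- function(link, iteration_limit = NULL, seed = 1L) {
  empty_trace <- data.frame(step = integer(0), residual_points = integer(0),
                            move_length = integer(0), component = integer(0),
                            i_s = integer(0), i_f = integer(0))
  if (!is.null(iteration_limit) && iteration_limit == 0L)
    return(list(link = link, trace = empty_trace, complete = FALSE))
  link <- ensure_general_position(link, seed = seed)
  if (is.null(iteration_limit)) iteration_limit <- 10L * nrow(link$points)
  M <- intersection_matrix(link)
  trace <- list()
  step <- 0L
  sweeps <- 0L
  base_link <- link; base_M <- M       # state before seam relabelling
  rot_round <- 0L
  repeat {
    if (sweeps >= iteration_limit)
      return(list(link = base_link, trace = trace_df(trace),
                  complete = FALSE))
    sweeps <- sweeps + 1L
    accepted_any <- FALSE
    i <- 1L
    while (i <= nrow(link$points)) {
      res <- grm(link, M, i)
      if (res$accepted) {
        link <- res$link; M <- res$matrix
        step <- step + 1L
        trace[[step]] <- c(step, nrow(link$points), res$move$length,
                           res$move$comp, res$move$i_s, res$move$i_f)
        accepted_any <- TRUE
        # restart at the same index
      } else {
        i <- i + 1L
      }
    }
    if (accepted_any) {
      base_link <- link; base_M <- M; rot_round <- 0L
      next
    }
    # fixpoint for this labelling and projection: first retry with
    # shifted seams on closed components (so seam-spanning subpaths are
    # considered), then with rigid rotations — a move blocked in one
    # projection may be admissible in another, the move itself is 3D
    rot_round <- rot_round + 1L
    # a crossing-free stalled diagram is already minimal (unlink
    # components at their smallest polygon): nothing to unlock
    if (rot_round > 6L || all(M == 0L))
      return(list(link = base_link, trace = trace_df(trace), complete = TRUE))
    if (rot_round <= 3L) {
      rotatable <- which(link$closed &
                         (c(link$sep[-1], nrow(link$points) + 1L) -
                          link$sep) > 3L)
      if (length(rotatable) == 0L) { rot_round <- 3L; next }
      for (k in rotatable) {
        n_k <- length(comp_points(link, k))
        link <- reroot_component(link, k, max(1L, n_k %/% 3L))
      }
    } else {
      rotated <- with_seed(seed * 131L + rot_round,
                           rotate_link(link, random_rotation()))
      rotated <- tryCatch(ensure_general_position(rotated,
                                                  seed = seed + rot_round),
                          error = function(e) NULL)
      if (is.null(rotated)) next
      link <- rotated
    }
    M <- intersection_matrix(link)
  }
}

trace_df <- function(trace) {
  if (length(trace) == 0L)
    return(data.frame(step = integer(0), residual_points = integer(0),
                      move_length = integer(0), component = integer(0),
                      i_s = integer(0), i_f = integer(0)))
  m <- do.call(rbind, trace)
  data.frame(step = m[, 1L], residual_points = m[, 2L],
             move_length = m[, 3L], component = m[, 4L],
             i_s = m[, 5L], i_f = m[, 6L])
}

#' Descriptive statistics of reduction traces
#'
#' @param traces a list of trace data.frames from [msr_reduce()].
#' @return list with `quartiles` (25/50/75%), `mean`,
#'   `zero_fraction` (share of moves of length 0), `n_moves`, and
#'   `pairs`, the per-step (residual length, move length) table for
#'   downstream trend analysis.
#' @export
move_stats <- function(traces) {
  if (length(traces) == 0L) stop("need at least one trace")
  if (is.data.frame(traces)) traces <- list(traces)
  lens <- unlist(lapply(traces, function(tr) tr$move_length))
  pairs <- do.call(rbind, lapply(traces, function(tr)
    data.frame(residual = tr$residual_points, move_length = tr$move_length)))
  if (length(lens) == 0L)
    return(list(quartiles = c(NA, NA, NA), mean = NaN, zero_fraction = NaN,
                n_moves = 0L, pairs = pairs))
  list(quartiles = stats::quantile(lens, c(0.25, 0.5, 0.75), names = FALSE),
       mean = mean(lens),
       zero_fraction = mean(lens == 0L),
       n_moves = length(lens),
       pairs = pairs)
}

#' Export a reduction trace as TSV
#'
#' @param trace a trace data.frame from [msr_reduce()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
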