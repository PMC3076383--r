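#' @title Geometric construction of Conway skein triples
#'
#' @description
#' Given a crossing of a reduced link diagram, the skein machinery
#' builds the other two members of the Conway triple directly on the
#' 3D structure:
#'
#' 1. a *clean quadrilateral* is grown around the crossing, with one
#'    vertex on each of the four cut edges, shrunk until its projection
#'    contains no other edge of the diagram (Xclean);
#' 2. the quadrilateral is *rotated* about the crossing point so that
#'    its sides are parallel to neither crossing edge, and the under
#'    strand is rerouted through the two rotated vertices on its cut
#'    edges (two-side replacement), validated by a topological check
#'    that no crossing with the remainder changed;
#' 3. the *switch* configuration replaces the rerouted under strand by
#'    a path through a perturbed copy of the point reflection of the
#'    underpass through the overpass, pulled towards the strand until
#'    the projection is regular and the one new crossing is an
#'    overpass (perturbation factor starts at 0.9 and converges to 1);
#' 4. the *smoothed* configuration reconnects the four cut strands
#'    through two opposite sides of the rotated quadrilateral
#'    (the oriented smoothing), which merges two components or splits
#'    one.
#'
#' Every construction is verified by a diagram diff: apart from the
#' processed crossing, the resulting diagram must have exactly the
#' same crossings (partners, over/under, signs) as the input.
#'
#' @name skein
NULL

# package-level audit trail for the perturbation/identity contracts
.skein_audit <- new.env(parent = emptyenv())
.skein_audit$switch_log <- list()
.skein_audit$enabled <- FALSE

#' Enable/disable and read the skein audit log
#'
#' When enabled, every [make_switch_config()] call appends a record
#' with the perturbation start value, its final value, and the
#' verification outcome.
#' @param on logical.
#' @return `skein_audit_log()` returns a data.frame of records.
#' @export
skein_audit_enable <- function(on = TRUE) {
  .skein_audit$enabled <- isTRUE(on)
  if (!.skein_audit$enabled) .skein_audit$switch_log <- list()
  invisible(.skein_audit$enabled)
}

#' @rdname skein_audit_enable
#' @export
skein_audit_reset <- function() {
  .skein_audit$switch_log <- list()
  invisible(NULL)
}

#' @rdname skein_audit_enable
#' @export
skein_audit_log <- function() {
  if (length(.skein_audit$switch_log) == 0L)
    return(data.frame(alpha_start = numeric(0), alpha_final = numeric(0),
                      changed_crossings = integer(0), overpass = logical(0)))
  do.call(rbind, lapply(.skein_audit$switch_log, as.data.frame))
}

# ---- crossing context ------------------------------------------------

crossing_context <- function(link, cr) {
  ed <- link_edges(link)
  P <- link$points
  eo <- cr$over_edge; eu <- cr$under_edge
  a1 <- ed[eo, 1L]; a2 <- ed[eo, 2L]
  b1 <- ed[eu, 1L]; b2 <- ed[eu, 2L]
  O3 <- P[a1, ] + cr$t_over * (P[a2, ] - P[a1, ])
  U3 <- P[b1, ] + cr$t_under * (P[b2, ] - P[b1, ])
  c2 <- c(cr$x, cr$y)
  cuts <- list(
    in_o  = list(far = a1, cut3 = O3),
    out_o = list(far = a2, cut3 = O3),
    in_u  = list(far = b1, cut3 = U3),
    out_u = list(far = b2, cut3 = U3))
  list(cr = cr, ed = ed, eo = eo, eu = eu,
       a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       O3 = O3, U3 = U3, c2 = c2, cuts = cuts)
}

quad_vertices <- function(link, ctx, t) {
  v3 <- matrix(NA_real_, 4L, 3L,
               dimnames = list(names(ctx$cuts), NULL))
  for (i in seq_len(4L)) {
    cu <- ctx$cuts[[i]]
    v3[i, ] <- cu$cut3 + t[i] * (link$points[cu$far, ] - cu$cut3)
  }
  v3
}

# does segment p-q (2D) touch any edge of the link projection other
# than the excluded ones?  Any contact within tolerance counts.
segment_hits_any <- function(link, excl, p, q, tolreg) {
  ed <- link_edges(link)
  ids <- setdiff(seq_len(nrow(ed)), excl)
  if (length(ids) == 0L) return(FALSE)
  P <- link$points
  P1 <- P[ed[ids, 1L], 1:2, drop = FALSE]
  P2 <- P[ed[ids, 2L], 1:2, drop = FALSE]
  n <- length(ids)
  A <- matrix(c(p, 0), n, 3L, byrow = TRUE)
  B <- matrix(c(q, 0), n, 3L, byrow = TRUE)
  d <- seg_dist3(A, B, cbind(P1, 0), cbind(P2, 0))
  any(d <= tolreg)
}

#' Incremental cleanness table of a polygon against a link projection
#'
#' Row i of the status table is the pair (entering side, leaving side)
#' of vertex i, each entry 1 when that polygon side touches the
#' projection of any non-excluded link edge and 0 otherwise.  Only the
#' sides adjacent to `touched` vertices are recomputed; the adjacent
#' rows that share those sides are updated accordingly, so the
#' incremental result always equals a full recomputation.
#'
#' @param polygon n x 2 matrix of polygon vertices in cyclic order.
#' @param link a `polygonal_link`.
#' @param status previous n x 2 status table, or `NULL` to compute all.
#' @param touched indices of vertices whose adjacent sides must be
#'   recomputed.
#' @param exclude_edges link edge ids exempt from the test (the two
#'   crossing edges, whose cut points lie on the polygon).
#' @return list `clean` (logical) and `status` (n x 2 matrix).
#' @export
xclean <- function(polygon, link, status = NULL,
                   touched = seq_len(nrow(polygon)),
                   exclude_edges = integer(0)) {
  n <- nrow(polygon)
  dg <- max(bbox_diag(link$points), 1e-12)
  tolreg <- 1e-9 * dg
  if (is.null(status)) {
    status <- matrix(NA_integer_, n, 2L)
    touched <- seq_len(n)
  }
  # side i joins vertex i to vertex i+1 (cyclic)
  sides <- unique(c((touched - 2L) %% n + 1L, (touched - 1L) %% n + 1L))
  for (s in sides) {
    hit <- segment_hits_any(link, exclude_edges,
                            polygon[s, ], polygon[s %% n + 1L, ], tolreg)
    status[s, 2L] <- as.integer(hit)            # leaving vertex s
    status[s %% n + 1L, 1L] <- as.integer(hit)  # entering vertex s+1
  }
  list(clean = all(status == 0L), status = status)
}

#' Build a clean quadrilateral around a crossing
#'
#' One vertex per cut edge, at parameter `t` of the way from the
#' crossing towards the far endpoint; all parameters start at 1 (the
#' full cut edges) and, while the quadrilateral projection still meets
#' other edges, the parameter of the longest dirty cut edge is halved.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param crossing one row of [find_crossings()] output.
#' @param max_halvings bail-out bound for the shrink loop.
#' @return an object of class `skein_quad`: crossing context, `t`
#'   parameters, 3D/2D vertices in the cyclic order around the
#'   crossing.
#' @export
build_clean_quadrilateral <- function(link, crossing, max_halvings = 60L) {
  ctx <- crossing_context(link, crossing)
  t <- rep(1, 4L)
  excl <- c(ctx$eo, ctx$eu)
  st <- NULL
  ord <- NULL
  for (iter in seq_len(max_halvings + 1L)) {
    v3 <- quad_vertices(link, ctx, t)
    ang <- atan2(v3[, 2L] - ctx$c2[2L], v3[, 1L] - ctx$c2[1L])
    ord <- order(ang)                     # cyclic order around the crossing
    poly <- v3[ord, 1:2, drop = FALSE]
    res <- xclean(poly, link, status = NULL, exclude_edges = excl)
    if (res$clean) {
      return(structure(list(ctx = ctx, t = t, v3 = v3, order = ord),
                       class = "skein_quad"))
    }
    # vertices with any dirty side, in original cut order
    dirty_cyc <- which(rowSums(res$status) > 0L)
    dirty <- ord[dirty_cyc]
    lens <- vapply(seq_len(4L), function(i)
      t[i] * sqrt(sum((link$points[ctx$cuts[[i]]$far, 1:2] - ctx$c2)^2)),
      0)
    cand <- dirty[which.max(lens[dirty])]
    t[cand] <- t[cand] / 2
  }
  link_error("no clean quadrilateral found: pathological clustering",
             "skeinpath_quadfail")
}

rotate_about <- function(v2, c2, theta) {
  co <- cos(theta); si <- sin(theta)
  dx <- v2[, 1L] - c2[1L]; dy <- v2[, 2L] - c2[2L]
  cbind(c2[1L] + co * dx - si * dy, c2[2L] + si * dx + co * dy)
}

#' Rotate a clean quadrilateral off the crossing edges
#'
#' Inserting the quadrilateral vertices directly would create edges
#' collinear with the cut edges; the quadrilateral is therefore
#' rotated about the crossing point.  The angle starts at half the
#' minimum of (a) the angle between the two projected crossing-edge
#' lines and (b) the smallest angular gap between consecutive cut
#' directions (so no vertex sweeps across another edge's position) and
#' is halved until the rotated quadrilateral is clean again.  Rotated
#' vertices keep the z of their unrotated lifts.
#'
#' @param link a `polygonal_link`.
#' @param quad a `skein_quad` from [build_clean_quadrilateral()].
#' @param crossing the same crossing row.
#' @param theta_start optional override of the initial angle.
#' @return list `quad_rot` (the quadrilateral with rotated vertices,
#'   field `v3r`) and `theta` (the accepted angle).
#' @export
rotate_quadrilateral <- function(link, quad, crossing, theta_start = NULL) {
  ctx <- quad$ctx
  P <- link$points
  d_o <- P[ctx$a2, 1:2] - P[ctx$a1, 1:2]
  d_u <- P[ctx$b2, 1:2] - P[ctx$b1, 1:2]
  ang_line <- function(d) atan2(d[2L], d[1L]) %% pi
  gap <- abs(ang_line(d_o) - ang_line(d_u))
  min_angle <- min(gap, pi - gap)
  dirs <- atan2(quad$v3[, 2L] - ctx$c2[2L], quad$v3[, 1L] - ctx$c2[1L])
  sd <- sort(dirs %% (2 * pi))
  gaps <- diff(c(sd, sd[1L] + 2 * pi))
  theta <- theta_start %||% (0.5 * min(min_angle, min(gaps)))
  excl <- c(ctx$eo, ctx$eu)
  for (iter in 1:60) {
    if (theta < 1e-12)
      link_error("rotation angle underflow", "skeinpath_rotfail")
    v2r <- rotate_about(quad$v3[, 1:2, drop = FALSE], ctx$c2, theta)
    v3r <- cbind(v2r, quad$v3[, 3L])
    rownames(v3r) <- rownames(quad$v3)
    poly <- v2r[quad$order, , drop = FALSE]
    ok <- xclean(poly, link, exclude_edges = excl)$clean
    if (ok) {
      # no side may be parallel to either crossing edge
      sidev <- poly[c(2:4, 1L), ] - poly
      par_o <- abs(cross2(sidev[, 1L], sidev[, 2L], d_o[1L], d_o[2L]))
      par_u <- abs(cross2(sidev[, 1L], sidev[, 2L], d_u[1L], d_u[2L]))
      sl <- sqrt(rowSums(sidev^2))
      lo <- sqrt(sum(d_o^2)); lu <- sqrt(sum(d_u^2))
      ok <- all(par_o > 1e-9 * sl * lo) && all(par_u > 1e-9 * sl * lu)
    }
    if (ok) {
      qr <- quad
      qr$v3r <- v3r
      qr$theta <- theta
      return(list(quad_rot = qr, theta = theta))
    }
    theta <- theta / 2
  }
  link_error("rotated quadrilateral never clean", "skeinpath_rotfail")
}

# ordered (edge, over) crossing signature of a polyline path against
# the link projection, excluding given edges; NULL if any crossing is
# degenerate (near a vertex / non-transversal)
path_signature <- function(link, excl, path3) {
  ed <- link_edges(link)
  ids <- setdiff(seq_len(nrow(ed)), excl)
  P <- link$points
  dg <- max(bbox_diag(P), 1e-12)
  tolreg <- 1e-7 * dg
  out_edge <- integer(0); out_over <- logical(0)
  for (s in seq_len(nrow(path3) - 1L)) {
    A <- path3[s, ]; B <- path3[s + 1L, ]
    if (length(ids) == 0L) next
    P1 <- P[ed[ids, 1L], , drop = FALSE]; P2 <- P[ed[ids, 2L], , drop = FALSE]
    rx <- B[1L] - A[1L]; ry <- B[2L] - A[2L]
    sx <- P2[, 1L] - P1[, 1L]; sy <- P2[, 2L] - P1[, 2L]
    qpx <- P1[, 1L] - A[1L]; qpy <- P1[, 2L] - A[2L]
    den <- cross2(rx, ry, sx, sy)
    lr <- sqrt(rx^2 + ry^2); ls <- sqrt(sx^2 + sy^2)
    par <- abs(den) <= 1e-12 * lr * ls
    t <- ifelse(par, NA_real_, cross2(qpx, qpy, sx, sy) / den)
    u <- ifelse(par, NA_real_, cross2(qpx, qpy, rx, ry) / den)
    hit <- which(!par & t > 0 & t < 1 & u > 0 & u < 1)
    if (length(hit)) {
      o <- order(t[hit])
      hit <- hit[o]
      zp <- A[3L] + t[hit] * (B[3L] - A[3L])
      ze <- P1[hit, 3L] + u[hit] * (P2[hit, 3L] - P1[hit, 3L])
      out_edge <- c(out_edge, ids[hit])
      out_over <- c(out_over, zp > ze)
    }
  }
  list(edge = out_edge, over = out_over)
}

#' Topological check of a two-side replacement
#'
#' Approves the replacement of the original cut edges by the
#' replacement path when (a) the dividing segment has no projected
#' intersections with the rest of the link and (b) the replacement
#' path meets the same edges of the rest, in the same order and with
#' identical over/under statuses, as the original cut edges.
#'
#' @param link the `polygonal_link` being operated on.
#' @param original_cut_edges 3-point matrix: the original two cut
#'   edges as the path (endpoint, cut point, endpoint).
#' @param replacement_path matrix of 3D points forming the candidate
#'   replacement.
#' @param dividing_segment 2-point matrix, or `NULL` to skip check (a).
#' @param exclude_edges edge ids not counted as "the rest" (the two
#'   crossing edges).
#' @return `TRUE` or `FALSE`.
#' @export
two_side_replacement_check <- function(link, original_cut_edges,
                                       replacement_path,
                                       dividing_segment = NULL,
                                       exclude_edges = integer(0)) {
  if (!is.null(dividing_segment)) {
    dg <- max(bbox_diag(link$points), 1e-12)
    if (segment_hits_any(link, exclude_edges,
                         dividing_segment[1L, 1:2],
                         dividing_segment[2L, 1:2], 1e-9 * dg))
      return(FALSE)
  }
  so <- path_signature(link, exclude_edges, original_cut_edges)
  sr <- path_signature(link, exclude_edges, replacement_path)
  identical(so$edge, sr$edge) && identical(so$over, sr$over)
}

# ---- surgery helpers -------------------------------------------------

# component point sequences of a link
link_seqs <- function(link) {
  lapply(seq_along(link$sep), function(k) comp_points(link, k))
}

# rebuild a link from explicit per-component coordinate blocks
assemble_link <- function(blocks, closed, origins) {
  sizes <- vapply(blocks, nrow, 1L)
  link <- build_link(do.call(rbind, blocks),
                     sep = cumsum(c(1L, sizes[-length(sizes)])),
                     closed = closed, check = FALSE)
  attr(link, "edge_origin") <- unlist(origins)
  link
}

# origin ids of the edges of component k (edge positions -> global ids)
comp_edge_ids <- function(link, k) {
  cm <- comp_meta(link)
  cm$eoff[k] + seq_len(cm$ecount[k])
}

# multiset diagram diff; `expect` is "switch" or "zero"
diagram_preserved <- function(old_link, old_cr, new_link, origin,
                              target, expect) {
  if (!isTRUE(is_regular(new_link))) return(FALSE)
  new_cr <- tryCatch(find_crossings(new_link), error = function(e) NULL)
  if (is.null(new_cr)) return(FALSE)
  oo <- origin[new_cr$over_edge]; ou <- origin[new_cr$under_edge]
  is_target_old <- (old_cr$over_edge == target$over_edge &
                    old_cr$under_edge == target$under_edge)
  key <- function(po, pu, sg) paste(po, pu, sg)
  old_keys <- key(old_cr$over_edge, old_cr$under_edge,
                  old_cr$sign)[!is_target_old]
  chord <- is.na(oo) | is.na(ou)
  if (expect == "zero") {
    if (any(chord)) return(FALSE)
    tgt_new <- (oo == target$over_edge & ou == target$under_edge) |
               (oo == target$under_edge & ou == target$over_edge)
    if (any(tgt_new)) return(FALSE)
    if (nrow(new_cr) != nrow(old_cr) - 1L) return(FALSE)
    new_keys <- key(oo, ou, new_cr$sign)
  } else {                      # switch
    if (any(chord)) return(FALSE)
    tgt_new <- (oo == target$over_edge & ou == target$under_edge) |
               (oo == target$under_edge & ou == target$over_edge)
    if (sum(tgt_new) != 1L) return(FALSE)
    # switched: old under strand now over, sign negated
    if (!(oo[tgt_new] == target$under_edge &&
          ou[tgt_new] == target$over_edge &&
          new_cr$sign[tgt_new] == -target$sign)) return(FALSE)
    if (nrow(new_cr) != nrow(old_cr)) return(FALSE)
    new_keys <- key(oo[!tgt_new], ou[!tgt_new], new_cr$sign[!tgt_new])
  }
  identical(sort(old_keys), sort(new_keys))
}

# replace edge `eid` by a path through `mids` (k x 3 matrix of new
# interior points); returns list(link, origin)
replace_edge_with_path <- function(link, eid, mids) {
  ed <- link_edges(link)
  comp <- ed[eid, 3L]
  seqs <- link_seqs(link)
  blocks <- list(); origins <- list(); closed <- link$closed
  for (k in seq_along(seqs)) {
    sq <- seqs[[k]]
    eids <- comp_edge_ids(link, k)
    if (k != comp) {
      blocks[[k]] <- link$points[sq, , drop = FALSE]
      origins[[k]] <- if (link$closed[k]) eids else eids
      next
    }
    le <- which(eids == eid)            # local edge position
    m <- length(sq)
    if (le < m || !link$closed[k]) {    # ordinary edge sq[le] -> sq[le+1]
      coords <- rbind(link$points[sq[seq_len(le)], , drop = FALSE],
                      mids,
                      link$points[sq[seq(le + 1L, m)], , drop = FALSE])
      org <- c(eids[seq_len(le - 1L)], rep(eid, nrow(mids) + 1L),
               if (le < length(eids)) eids[seq(le + 1L, length(eids))])
    } else {                            # closing edge sq[m] -> sq[1]
      coords <- rbind(link$points[sq, , drop = FALSE], mids)
      org <- c(eids[seq_len(m - 1L)], rep(eid, nrow(mids) + 1L))
    }
    blocks[[k]] <- coords
    origins[[k]] <- org
  }
  out <- assemble_link(blocks, closed, origins)
  list(link = out, origin = attr(out, "edge_origin"))
}

# cyclic walk of a closed component from point index `from` to `to`
# (inclusive), returning the positions in traversal order
cyclic_walk <- function(sq, from, to) {
  i <- match(from, sq); j <- match(to, sq)
  n <- length(sq)
  if (i <= j) sq[i:j] else sq[c(i:n, 1:j)]
}

# edge id connecting consecutive points p -> next within component k
edge_between <- function(link, k, p) {
  sq <- comp_points(link, k)
  lp <- match(p, sq)
  comp_edge_ids(link, k)[lp]
}

#' Switched skein configuration (the crossing change)
#'
#' Builds the member of the Conway triple in which the selected
#' crossing is switched: the under strand, rerouted through the
#' rotated quadrilateral, is lifted through a perturbed copy of the
#' point reflection of the underpass through the overpass.  The
#' perturbation factor alpha starts at 0.9 and is pushed towards 1
#' (`alpha <- (1+alpha)/2`) until the projection is regular, exactly
#' one crossing changed, and the new crossing is an overpass.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param crossing one row of [find_crossings()].
#' @param quad_rot optional pre-computed rotation
#'   ([rotate_quadrilateral()] output); built on demand.
#' @return the switched `polygonal_link`.
#' @export
make_switch_config <- function(link, crossing, quad_rot = NULL) {
  old_cr <- find_crossings(link)
  if (is.null(quad_rot)) {
    quad <- build_clean_quadrilateral(link, crossing)
    quad_rot <- rotate_quadrilateral(link, quad, crossing)$quad_rot
  }
  theta <- quad_rot$theta
  for (round in 1:12) {
    res <- try_switch(link, old_cr, crossing, quad_rot)
    if (!is.null(res)) return(res)
    # re-rotate with a smaller angle and retry
    theta <- theta / 2
    quad_rot <- rotate_quadrilateral(link, quad_rot, crossing,
                                     theta_start = theta)$quad_rot
  }
  link_error("switch configuration never verified", "skeinpath_perturbfail")
}

try_switch <- function(link, old_cr, crossing, quad_rot) {
  ctx <- quad_rot$ctx
  vin_u <- quad_rot$v3r["in_u", ]; vout_u <- quad_rot$v3r["out_u", ]
  # crossing of the rerouted middle segment with the over edge
  P <- link$points
  A2d <- vin_u[1:2]; B2d <- vout_u[1:2]
  p1 <- P[ctx$a1, ]; p2 <- P[ctx$a2, ]
  den <- cross2(B2d[1] - A2d[1], B2d[2] - A2d[2],
                p2[1] - p1[1], p2[2] - p1[2])
  if (abs(den) < 1e-300) return(NULL)
  tq <- cross2(p1[1] - A2d[1], p1[2] - A2d[2],
               p2[1] - p1[1], p2[2] - p1[2]) / den
  uq <- cross2(p1[1] - A2d[1], p1[2] - A2d[2],
               B2d[1] - A2d[1], B2d[2] - A2d[2]) / den
  if (!(tq > 0 && tq < 1 && uq > 0 && uq < 1)) return(NULL)
  U3q <- vin_u + tq * (vout_u - vin_u)
  O3q <- p1 + uq * (p2 - p1)
  W <- 2 * O3q - U3q
  # ordered topological check: the rerouted outer pieces must meet the
  # same edges, in the same order, with the same statuses as the
  # original cut edges of the under strand
  Pb1 <- P[ctx$b1, ]; Pb2 <- P[ctx$b2, ]
  both <- c(ctx$eo, ctx$eu)    # the crossing itself is checked globally
  sig_eq <- function(a, b) identical(a$edge, b$edge) &&
                           identical(a$over, b$over)
  if (!sig_eq(path_signature(link, both, rbind(Pb1, ctx$U3)),
              path_signature(link, both, rbind(Pb1, vin_u))))
    return(NULL)
  if (!sig_eq(path_signature(link, both, rbind(ctx$U3, Pb2)),
              path_signature(link, both, rbind(vout_u, Pb2))))
    return(NULL)
  alpha <- 0.9; alpha_start <- alpha
  repeat {
    pp <- vout_u + alpha * (W - vout_u)
    mids <- rbind(vin_u, pp, vout_u)
    cand <- try(replace_edge_with_path(link, ctx$eu, mids), silent = TRUE)
    ok <- FALSE
    if (!inherits(cand, "try-error")) {
      simple_ok <- nrow(nonsimple_pairs(cand$link)) == 0L
      ok <- simple_ok &&
        diagram_preserved(link, old_cr, cand$link, cand$origin,
                          crossing, "switch")
    }
    if (ok) {
      if (.skein_audit$enabled) {
        .skein_audit$switch_log[[length(.skein_audit$switch_log) + 1L]] <-
          list(alpha_start = alpha_start, alpha_final = alpha,
               changed_crossings = 1L, overpass = TRUE)
      }
      return(cand$link)
    }
    if (1 - alpha < 1e-12) return(NULL)
    alpha <- (1 + alpha) / 2
  }
}

#' Smoothed skein configuration (oriented smoothing)
#'
#' Replaces the two crossing edges by the oriented reconnection
#' through the rotated quadrilateral vertices: the incoming strand of
#' each edge is joined to the outgoing strand of the other through a
#' side of the rotated quadrilateral.  A self-crossing splits its
#' component in two; a crossing between two components merges them.
#'
#' @param link a `polygonal_link` with regular projection.
#' @param crossing one row of [find_crossings()].
#' @param quad_rot a rotation result (`quad_rot` field of
#'   [rotate_quadrilateral()]); built on demand when `NULL`.
#' @return the smoothed `polygonal_link`.
#' @export
make_zero_config <- function(link, crossing, quad_rot = NULL) {
  old_cr <- find_crossings(link)
  if (is.null(quad_rot)) {
    quad <- build_clean_quadrilateral(link, crossing)
    quad_rot <- rotate_quadrilateral(link, quad, crossing)$quad_rot
  }
  theta <- quad_rot$theta
  for (round in 1:12) {
    res <- try_zero(link, old_cr, crossing, quad_rot)
    if (!is.null(res)) return(res)
    theta <- theta / 2
    quad_rot <- rotate_quadrilateral(link, quad_rot, crossing,
                                     theta_start = theta)$quad_rot
  }
  link_error("smoothed configuration never verified", "skeinpath_zerofail")
}

try_zero <- function(link, old_cr, crossing, quad_rot) {
  ctx <- quad_rot$ctx
  V <- quad_rot$v3r
  ko <- comp_of_point(link, ctx$a1); ku <- comp_of_point(link, ctx$b1)
  if (!link$closed[ko] || !link$closed[ku])
    link_error("oriented smoothing needs closed components; close the link",
               "skeinpath_openlink")
  P <- link$points
  V4 <- V
  # ordered topological check on all four rerouted cut pieces and the
  # two reconnection chords (which are sides of the clean rotated
  # quadrilateral, hence expected crossing-free)
  sig_eq <- function(a, b) identical(a$edge, b$edge) &&
                           identical(a$over, b$over)
  both <- c(ctx$eo, ctx$eu)    # the crossing itself is checked globally
  checks <- list(
    list(rbind(P[ctx$a1, ], ctx$O3), rbind(P[ctx$a1, ], V4["in_o", ])),
    list(rbind(ctx$O3, P[ctx$a2, ]), rbind(V4["out_o", ], P[ctx$a2, ])),
    list(rbind(P[ctx$b1, ], ctx$U3), rbind(P[ctx$b1, ], V4["in_u", ])),
    list(rbind(ctx$U3, P[ctx$b2, ]), rbind(V4["out_u", ], P[ctx$b2, ])))
  for (chk in checks) {
    if (!sig_eq(path_signature(link, both, chk[[1]]),
                path_signature(link, both, chk[[2]])))
      return(NULL)
  }
  for (chord in list(rbind(V4["in_o", ], V4["out_u", ]),
                     rbind(V4["in_u", ], V4["out_o", ]))) {
    s <- path_signature(link, both, chord)
    if (length(s$edge) > 0L) return(NULL)
  }
  seqs <- link_seqs(link)
  blocks <- list(); origins <- list(); closed <- c()
  walk_coords <- function(k, from, to) {
    w <- cyclic_walk(seqs[[k]], from, to)
    eids <- vapply(w[-length(w)], function(p) edge_between(link, k, p), 0L)
    list(coords = P[w, , drop = FALSE], eids = eids)
  }
  if (ko == ku) {
    w1 <- walk_coords(ko, ctx$a2, ctx$b1)
    w2 <- walk_coords(ko, ctx$b2, ctx$a1)
    # comp1: a2 .. b1, vin_u, vout_o, (close -> a2)
    b1coords <- rbind(w1$coords, V["in_u", ], V["out_o", ])
    b1orig <- c(w1$eids, ctx$eu, NA_integer_, ctx$eo)
    # comp2: b2 .. a1, vin_o, vout_u, (close -> b2)
    b2coords <- rbind(w2$coords, V["in_o", ], V["out_u", ])
    b2orig <- c(w2$eids, ctx$eo, NA_integer_, ctx$eu)
    for (k in seq_along(seqs)) {
      if (k == ko) {
        blocks <- c(blocks, list(b1coords, b2coords))
        origins <- c(origins, list(b1orig, b2orig))
        closed <- c(closed, TRUE, TRUE)
      } else {
        blocks <- c(blocks, list(P[seqs[[k]], , drop = FALSE]))
        origins <- c(origins, list(comp_edge_ids(link, k)))
        closed <- c(closed, link$closed[k])
      }
    }
  } else {
    wu <- walk_coords(ku, ctx$b2, ctx$b1)
    wo <- walk_coords(ko, ctx$a2, ctx$a1)
    coords <- rbind(wu$coords, V["in_u", ], V["out_o", ],
                    wo$coords, V["in_o", ], V["out_u", ])
    orig <- c(wu$eids, ctx$eu, NA_integer_, ctx$eo,
              wo$eids, ctx$eo, NA_integer_, ctx$eu)
    first <- min(ko, ku)
    for (k in seq_along(seqs)) {
      if (k == first) {
        blocks <- c(blocks, list(coords))
        origins <- c(origins, list(orig))
        closed <- c(closed, TRUE)
      } else if (k == ko || k == ku) {
        next
      } else {
        blocks <- c(blocks, list(P[seqs[[k]], , drop = FALSE]))
        origins <- c(origins, list(comp_edge_ids(link, k)))
        closed <- c(closed, link$closed[k])
      }
    }
  }
  cand <- try(assemble_link(blocks, closed, origins), silent = TRUE)
  if (inherits(cand, "try-error")) return(NULL)
  if (nrow(nonsimple_pairs(cand)) > 0L) return(NULL)
  if (!diagram_preserved(link, old_cr, cand, attr(cand, "edge_origin"),
                         crossing, "zero")) return(NULL)
  cand
}

# ---- crossing selection and the skein tree ---------------------------

# crossings first met as an underpass, in traversal order
under_candidates <- function(link, cr = find_crossings(link)) {
  if (nrow(cr) == 0L) return(integer(0))
  pass <- data.frame(crossing = rep(seq_len(nrow(cr)), 2L),
                     edge = c(cr$over_edge, cr$under_edge),
                     t = c(cr$t_over, cr$t_under),
                     over = rep(c(TRUE, FALSE), each = nrow(cr)))
  pass <- pass[order(pass$edge, pass$t), ]
  first <- !duplicated(pass$crossing)
  pass$crossing[first & !pass$over]
}

#' Select the crossing to be processed next
#'
#' Candidates are the crossings first met as an underpass along the
#' traversal; switching these progresses towards a descending diagram.
#' The `fixed` strategy takes the first candidate in traversal order;
#' `greedy` switches each candidate, reduces the result with MSR, and
#' picks the one with the fewest residual points (ties broken by
#' traversal order).
#'
#' @param link a reduced `polygonal_link` with regular projection.
#' @param strategy `"greedy"` or `"fixed"`.
#' @param seed seed forwarded to the trial reductions.
#' @return `NULL` when the diagram is descending (no candidate);
#'   otherwise a list with `crossing` (row of [find_crossings()]) and,
#'   for the greedy strategy, `switched` (the winning reduced switch
#'   configuration, reusable by the caller).
#' @export
select_crossing <- function(link, strategy = c("greedy", "fixed"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  cr <- find_crossings(link)
  cands <- under_candidates(link, cr)
  if (length(cands) == 0L) return(NULL)
  if (strategy == "fixed")
    return(list(crossing = cr[cands[1L], ], switched = NULL))
  best <- NULL
  for (ci in cands) {
    sw <- try(make_switch_config(link, cr[ci, ]), silent = TRUE)
    if (inherits(sw, "try-error")) next
    red <- msr_reduce(sw, seed = seed)
    np <- nrow(red$link$points)
    if (is.null(best) || np < best$np) {
      best <- list(crossing = cr[ci, ], switched = red$link, np = np)
    }
  }
  if (is.null(best))           # fall back to the fixed choice
    return(list(crossing = cr[cands[1L], ], switched = NULL))
  best[c("crossing", "switched")]
}

#' Build the skein tree of a link
#'
#' The root is the MSR-reduced input.  Recursively, a crossing is
#' selected, its skein sign recorded, and the switched and smoothed
#' configurations attached as children after their own MSR reduction;
#' leaves are descending diagrams (unlinks).
#'
#' @param link a simple `polygonal_link` (general position ensured).
#' @param strategy crossing selection strategy, `"greedy"` or
#'   `"fixed"`.
#' @param seed seed for general positioning and trial reductions.
#' @param max_depth recursion guard (default 64).
#' @return an object of class `skein_tree`: `root` (nested nodes with
#'   fields `link`, `ncomp`, `npoints`, `epsilon`, `children`), `g`
#'   (number of levels below the root) and `nu` (node count).
#' @export
build_skein_tree <- function(link, strategy = c("greedy", "fixed"),
                             seed = 1L, max_depth = 64L) {
  strategy <- match.arg(strategy)
  root_link <- msr_reduce(link, seed = seed)$link
  rec <- function(lnk, depth) {
    if (depth > max_depth)
      stop("skein recursion exceeded max_depth = ", max_depth)
    last_err <- NULL
    for (attempt in 0:4) {
      if (attempt > 0L) {
        # re-perturb globally: a fresh rigid rotation gives a new
        # diagram of the same link and new room for the constructions
        lnk <- with_seed(seed * 977L + depth * 31L + attempt,
                         rotate_link(lnk, random_rotation()))
      }
      # a reduction can also leave two crossings nearly coincident; a
      # rotation restores regularity without changing the isotopy class
      lnk <- ensure_general_position(lnk, seed = seed + attempt)
      sel <- select_crossing(lnk, strategy, seed = seed)
      if (is.null(sel)) {
        return(list(link = lnk, ncomp = link_ncomp(lnk),
                    npoints = nrow(lnk$points), epsilon = 0L,
                    children = NULL))
      }
      crx <- sel$crossing
      built <- tryCatch({
        quad <- build_clean_quadrilateral(lnk, crx)
        qr <- rotate_quadrilateral(lnk, quad, crx)$quad_rot
        sw <- if (!is.null(sel$switched) && attempt == 0L) sel$switched
              else msr_reduce(make_switch_config(lnk, crx, qr),
                              seed = seed)$link
        zr <- msr_reduce(make_zero_config(lnk, crx, qr), seed = seed)$link
        list(sw = sw, zr = zr)
      }, skeinpath_quadfail = function(e) e, skeinpath_rotfail = function(e) e,
         skeinpath_perturbfail = function(e) e,
         skeinpath_zerofail = function(e) e)
      if (inherits(built, "condition")) { last_err <- built; next }
      return(list(link = lnk, ncomp = link_ncomp(lnk),
                  npoints = nrow(lnk$points),
                  epsilon = as.integer(crx$sign),
                  children = list(switch = rec(built$sw, depth + 1L),
                                  zero = rec(built$zr, depth + 1L))))
    }
    stop("skein construction failed after re-perturbation: ",
         conditionMessage(last_err))
  }
  root <- rec(root_link, 0L)
  depth_of <- function(nd) {
    if (is.null(nd$children)) 0L
    else 1L + max(depth_of(nd$children$switch), depth_of(nd$children$zero))
  }
  count_of <- function(nd) {
    if (is.null(nd$children)) 1L
    else 1L + count_of(nd$children$switch) + count_of(nd$children$zero)
  }
  structure(list(root = root, g = depth_of(root), nu = count_of(root),
                 strategy = strategy),
            class = "skein_tree")
}

#' @export
print.skein_tree <- function(x, ...) {
  cat(sprintf("<skein_tree> strategy=%s levels g=%d nodes nu=%d\n",
              x$strategy, x$g, x$nu))
  invisible(x)
}

#' Bottom-up weight propagation through a skein tree
#'
#' Leaves (descending diagrams) receive the unlink polynomial of their
#' component count; an inner node carrying skein sign epsilon combines
#' its children by the skein recursion
#' `P = -l^(-2 eps) P_switch - l^(-eps) m P_zero`.
#'
#' @param tree a `skein_tree`.
#' @return the root weight, a `laurent2` polynomial.
#' @export
propagate_weights <- function(tree) {
  node_weight(tree$root)
}

node_weight <- function(nd) {
  if (is.null(nd$children)) return(unlink_poly(nd$ncomp))
  if (is.null(nd$epsilon) || nd$epsilon == 0L)
    stop("incomplete skein tree: inner node without a skein sign")
  skein_combine(nd$epsilon,
                node_weight(nd$children$switch),
                node_weight(nd$children$zero))
}

#' Verify the skein identity at every inner node of a tree
#'
#' For each processed crossing the three geometric configurations
#' (node, switch child, zero child) are re-evaluated independently by
#' the diagrammatic oracle and the identity
#' `l*P(L+) + l^-1*P(L-) + m*P(L0) = 0` is checked symbolically.
#'
#' @param tree a `skein_tree`.
#' @return data.frame with one row per inner node: `epsilon` and
#'   `identity_ok`.
#' @export
verify_skein_identities <- function(tree) {
  rows <- list()
  rec <- function(nd) {
    if (is.null(nd$children)) return(invisible(NULL))
    pn <- homfly_from_diagram(gauss_code(nd$link))
    ps <- homfly_from_diagram(gauss_code(nd$children$switch$link))
    pz <- homfly_from_diagram(gauss_code(nd$children$zero$link))
    if (nd$epsilon == 1L) { pplus <- pn; pminus <- ps }
    else { pplus <- ps; pminus <- pn }
    resid <- l2_add(l2_add(l2_mul(l2_mono(1, 1L, 0L), pplus),
                           l2_mul(l2_mono(1, -1L, 0L), pminus)),
                    l2_mul(l2_mono(1, 0L, 1L), pz))
    rows[[length(rows) + 1L]] <<- data.frame(
      epsilon = nd$epsilon, identity_ok = l2_is_zero(resid))
    rec(nd$children$switch); rec(nd$children$zero)
  }
  rec(tree$root)
  if (length(rows) == 0L)
    return(data.frame(epsilon = integer(0), identity_ok = logical(0)))
  do.call(rbind, rows)
}

#' Export a skein tree as JSON
#'
#' @param tree a `skein_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
skein_tree_json <- function(tree, path) {
  id <- 0L
  nodes <- list()
  rec <- function(nd) {
    id <<- id + 1L
    me <- id
    rec_children <- if (!is.null(nd$children)) {
      sw <- rec(nd$children$switch)
      ze <- rec(nd$children$zero)
      c(sw, ze)
    } else NULL
    nodes[[me]] <<- list(id = me, npoints = nd$npoints, ncomp = nd$ncomp,
                         epsilon = nd$epsilon,
                         children = if (is.null(rec_children)) NULL
                                    else rec_children)
    me
  }
  rec(tree$root)
  jsonlite::write_json(list(strategy = tree$strategy, g = tree$g,
                            nu = tree$nu, nodes = nodes),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' HOMFLY polynomial of a polygonal link (geometric pipeline)
#'
#' Full pipeline: general positioning, MSR reduction, skein tree
#' construction with geometric Conway triples, bottom-up weight
#' propagation.  Convention `l*P(L+) + l^-1*P(L-) + m*P(L0) = 0`,
#' `P(unknot) = 1`.
#'
#' @param link a simple `polygonal_link` with closed components (close
#'   open chains first, e.g. with [close_and_classify()]).
#' @param strategy crossing selection strategy.
#' @param seed controls general-position rotations; the result is
#'   invariant across seeds.
#' @return a `laurent2` polynomial.
#' @export
homfly <- function(link, strategy = c("greedy", "fixed"), seed = 1L) {
  strategy <- match.arg(strategy)
  propagate_weights(build_skein_tree(link, strategy, seed = seed))
}
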