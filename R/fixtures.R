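#' @title Deterministic fixture generator
#'
#' @description
#' Parametric knots and links used as a download-free test surface:
#' torus knots, the figure-eight knot, twist knots built as closed
#' braids, Hopf links, unlinks, minimal stick representations,
#' connected sums, split unions, and random protein-like open chains.
#' Every fixture is bit-reproducible from its arguments.
#'
#' @name fixtures
NULL

#' Closed-braid polygonal realization
#'
#' Builds a polygonal link realizing the closure of a braid word.
#' Letter `+k` produces a crossing of oriented sign +1 between the
#' strands at positions `k` and `k+1`; `-k` a sign -1 crossing.  The
#' closure arcs are nested rectangles that introduce no extra
#' crossings, so the diagram of the result has exactly one crossing
#' per letter.
#'
#' @param word integer vector of nonzero letters, `abs(word) < strands`.
#' @param strands number of braid strands.
#' @return a closed `polygonal_link` (one component per permutation
#'   cycle of the word).
#' @export
fixture_braid <- function(word, strands = max(abs(word)) + 1L) {
  stopifnot(length(word) >= 1L, all(word != 0L), all(abs(word) < strands))
  L <- length(word)
  h <- 0.4
  # per-strand polyline through the braid; strand s starts at (0, s, 0)
  pos <- seq_len(strands)             # pos[s] = current position of strand s
  paths <- lapply(seq_len(strands), function(s) matrix(c(0, s, 0), 1L, 3L))
  for (j in seq_len(L)) {
    k <- abs(word[j]); positive <- word[j] > 0L
    s_lo <- which(pos == k); s_hi <- which(pos == k + 1L)
    # sign +1 <=> the descending strand (k+1 -> k) passes over
    over_desc <- positive
    for (s in seq_len(strands)) {
      p <- pos[s]
      if (s == s_lo) {          # ascending strand k -> k+1
        z <- if (over_desc) -h else h
        mid <- c(j - 1 + 0.45, k + 0.45, z)
        paths[[s]] <- rbind(paths[[s]], mid, c(j, k + 1, 0))
      } else if (s == s_hi) {   # descending strand k+1 -> k
        z <- if (over_desc) h else -h
        mid <- c(j - 1 + 0.55, k + 0.45, z)
        paths[[s]] <- rbind(paths[[s]], mid, c(j, k, 0))
      } else {
        paths[[s]] <- rbind(paths[[s]], c(j, p, 0))
      }
    }
    pos[s_lo] <- k + 1L; pos[s_hi] <- k
  }
  # closure arc for slot p: from (L, p) around to (0, p), margin
  # decreasing with p so the nested rectangles stay disjoint
  arc <- function(p) {
    cmar <- 0.6 * (strands + 1 - p)
    rbind(c(L + cmar, p, 0), c(L + cmar, strands + cmar, 0),
          c(-cmar, strands + cmar, 0), c(-cmar, p, 0))
  }
  # assemble components by following braid strands and closure arcs
  endpos <- pos                        # final position of each strand
  used <- rep(FALSE, strands)
  comp_pts <- list()
  for (s0 in seq_len(strands)) {
    if (used[s0]) next
    pts <- NULL
    s <- s0
    repeat {
      used[s] <- TRUE
      pts <- rbind(pts, paths[[s]], arc(endpos[s]))
      s_next <- endpos[s]              # arc lands at (0, endpos[s])
      if (s_next == s0) break
      s <- s_next
    }
    comp_pts[[length(comp_pts) + 1L]] <- pts
  }
  sizes <- vapply(comp_pts, nrow, 1L)
  build_link(do.call(rbind, comp_pts),
             sep = cumsum(c(1L, sizes[-length(sizes)])),
             closed = TRUE)
}

#' Parametric and template knot/link fixtures
#'
#' @param p,q torus knot winding numbers (coprime).
#' @param n number of sample points.
#' @return a `polygonal_link`.
#' @details `fixture_torus_knot(2, 3, ...)` with this parametrization is
#'   the package's handedness anchor: it is designated the
#'   right-handed trefoil and all L/R labels in the knot table derive
#'   from it.
#' @export
fixture_torus_knot <- function(p = 2L, q = 3L, n = 60L) {
  # phase offset avoids the exact symmetric vertex coincidences of the
  # unshifted uniform sample
  t <- 2 * pi * (seq(0L, n - 1L) + 0.32) / n
  pts <- cbind((2 + cos(q * t)) * cos(p * t),
               (2 + cos(q * t)) * sin(p * t),
               -sin(q * t))
  tryCatch(build_link(pts, closed = TRUE),
           skeinpath_nonsimple = function(e)
             stop("torus knot undersampled at n = ", n,
                  "; increase n_points"))
}

#' @param n number of sample points.
#' @rdname fixture_torus_knot
#' @export
fixture_figure_eight <- function(n = 100L) {
  t <- 2 * pi * (seq(0L, n - 1L) + 0.32) / n
  pts <- cbind((2 + cos(2 * t)) * cos(3 * t),
               (2 + cos(2 * t)) * sin(3 * t),
               sin(4 * t))
  tryCatch(build_link(pts, closed = TRUE),
           skeinpath_nonsimple = function(e)
             stop("figure-eight undersampled at n = ", n,
                  "; increase n_points"))
}

# braid words for twist knots (verified in the test suite against the
# Alexander polynomial / determinant of each knot type)
twist_words <- list(
  `1` = c(1L, 1L, 1L),                      # 3_1
  `2` = c(1L, -2L, 1L, -2L),                # 4_1
  `3` = c(1L, 1L, 1L, 2L, -1L, 2L),         # 5_2
  `4` = c(1L, 1L, 2L, -1L, -3L, 2L, -3L)    # 6_1 (Stevedore)
)

#' @param k number of half-twists in the twist region: 1 gives the
#'   trefoil, 2 the figure-eight, 3 the three-twist knot (5_2), 4 the
#'   Stevedore knot (6_1).
#' @rdname fixture_torus_knot
#' @export
fixture_twist_knot <- function(k) {
  w <- twist_words[[as.character(k)]]
  if (is.null(w)) stop("twist knot template available for k in 1..4")
  fixture_braid(w)
}

#' @param sign +1 or -1: sign of the two crossings of the Hopf link.
#' @rdname fixture_torus_knot
#' @export
fixture_hopf <- function(sign = 1L) {
  stopifnot(sign %in% c(-1L, 1L))
  fixture_braid(c(sign, sign), strands = 2L)
}

#' @param k number of components of the unlink.
#' @rdname fixture_torus_knot
#' @export
fixture_unlink <- function(k = 2L) {
  stopifnot(k >= 1L)
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  pts <- do.call(rbind, lapply(seq_len(k), function(i) {
    s <- sq; s[, 1L] <- s[, 1L] + 3 * (i - 1L); s
  }))
  build_link(pts, sep = seq(1L, by = 4L, length.out = k), closed = TRUE)
}

#' Minimal stick representations
#'
#' Hard-coded minimal polygonal forms: a 6-stick trefoil (6 is the
#' stick number of the trefoil, so this realization is minimal) and a
#' 7-stick figure-eight (stick number 7).  The trefoil coordinates are
#' the MSR-reduced 60-point torus fixture, hence right-handed by the
#' package's handedness anchor; both knot types are verified against
#' the diagrammatic oracle in the test suite.
#'
#' @return a closed `polygonal_link`.
#' @export
fixture_stick_trefoil <- function() {
  pts <- matrix(c(
     0.4279, -2.4668, -0.8639,
     1.0436,  0.2961,  0.4029,
    -2.0914,  2.0309, -0.4029,
     0.2557, -1.4744,  0.8639,
     2.9882,  0.2006, -0.1004,
    -1.4047,  0.5157,  0.8639), ncol = 3L, byrow = TRUE)
  build_link(pts, closed = TRUE)
}

#' @rdname fixture_stick_trefoil
#' @export
fixture_stick_figure_eight <- function() {
  pts <- matrix(c(
    -0.7054,  0.0761,  0.1598,
     0.3256, -0.4537, -0.6451,
    -0.6804, -0.3744, -0.3404,
     0.0553, -0.0135, -0.7945,
    -0.2460, -0.8987,  0.5286,
     0.4961,  0.0125,  0.1449,
    -0.2243, -0.1104, -0.8987), ncol = 3L, byrow = TRUE)
  build_link(pts, closed = TRUE)
}

#' Random protein-like open chain
#'
#' Self-avoiding random walk with fixed 3.8 Angstrom steps (the
#' C-alpha virtual bond length) and a 3.0 Angstrom excluded-volume
#' floor between non-neighbour points.  `helix_mix` interleaves
#' alpha-helix-like stretches (1.5 A rise, 100 degree turn on a 2.3 A
#' radius) with random coil.
#'
#' @param n number of points (`n >= 4`).
#' @param seed integer seed; the chain is a pure function of
#'   `(n, seed, style)`.
#' @param style `"walk"` or `"helix_mix"`.
#' @return an open single-component `polygonal_link`.
#' @export
random_chain <- function(n, seed = 1L, style = c("walk", "helix_mix")) {
  style <- match.arg(style)
  stopifnot(n >= 4L)
  step <- 3.8; dmin <- 3.0
  with_seed(seed, {
    for (attempt in 1:50) {
      pts <- matrix(NA_real_, n, 3L)
      pts[1L, ] <- c(0, 0, 0)
      dir <- c(1, 0, 0)
      pts[2L, ] <- pts[1L, ] + step * dir
      helix_phase <- 0
      in_helix <- FALSE
      ok <- TRUE
      for (i in 3:n) {
        placed <- FALSE
        if (style == "helix_mix") {
          if (stats::runif(1) < 0.1) in_helix <- !in_helix
        }
        for (try in 1:100) {
          if (style == "helix_mix" && in_helix && try == 1L) {
            # bond/torsion angles approximating an alpha helix trace
            prop <- propose_angles(pts[i - 2L, ], pts[i - 1L, ], step,
                                   theta = 89 * pi / 180,
                                   phi = 50 * pi / 180)
          } else {
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            prop <- pts[i - 1L, ] + step * u
          }
          d2 <- sqrt(rowSums((pts[seq_len(i - 2L), , drop = FALSE] -
                              matrix(prop, i - 2L, 3L, byrow = TRUE))^2))
          if (all(d2 >= dmin)) { pts[i, ] <- prop; placed <- TRUE; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(build_link(pts, closed = FALSE))
    }
    stop("self-avoiding walk placement failed; try another seed")
  })
}

# place the next point at bond angle theta / torsion phi from the
# last two points
propose_angles <- function(a, b, step, theta, phi) {
  v <- b - a; v <- v / sqrt(sum(v^2))
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * v) * v; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  d <- cos(pi - theta) * v +
    sin(pi - theta) * (cos(phi) * e1 + sin(phi) * e2)
  b + step * d
}

#' All flips of a link
#'
#' Mirror image and orientation reversals: the 2^(c+1) combinations of
#' {identity, mirror} with per-component orientation reversal, where c
#' is the component count.
#'
#' @param link a `polygonal_link`.
#' @return a list of `polygonal_link` objects in a deterministic
#'   order; element 1 is the input itself.
#' @export
flips <- function(link) {
  nc <- link_ncomp(link)
  out <- list()
  for (mir in c(FALSE, TRUE)) {
    base <- if (mir) mirror_link(link) else link
    for (mask in 0:(2^nc - 1)) {
      comps <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0L)
      out[[length(out) + 1L]] <-
        if (length(comps)) reverse_link(base, comps) else base
    }
  }
  out
}

#' Connected sum and split union of closed links
#'
#' `connected_sum` excises one edge from each single-component closed
#' knot and joins the loose ends with two bridging segments on the
#' facing sides of the translated-apart copies.  `split_union` simply
#' places the two links far apart in one object.
#'
#' @param k1,k2 closed single-component `polygonal_link`s.
#' @return a `polygonal_link`.
#' @export
connected_sum <- function(k1, k2) {
  stopifnot(link_ncomp(k1) == 1L, k1$closed[1L],
            link_ncomp(k2) == 1L, k2$closed[1L])
  for (variant in 1:4) {
    kk2 <- k2
    if (variant %in% c(2L, 4L)) kk2 <- reverse_link(kk2)
    if (variant %in% c(3L, 4L)) {
      # flip second summand around the y axis (keeps knot type)
      kk2$points[, 1L] <- -kk2$points[, 1L]
      kk2$points[, 3L] <- -kk2$points[, 3L]
    }
    cand <- try(connected_sum_try(k1, kk2), silent = TRUE)
    if (!inherits(cand, "try-error")) return(cand)
  }
  stop("could not construct a collision-free connected sum")
}

connected_sum_try <- function(k1, k2) {
  p1 <- k1$points; p2 <- k2$points
  gap <- 4 + 0.5 * (bbox_diag(p1) + bbox_diag(p2))
  shift <- max(p1[, 1L]) - min(p2[, 1L]) + gap
  p2[, 1L] <- p2[, 1L] + shift
  n1 <- nrow(p1); n2 <- nrow(p2)
  # cut the edge with the largest x midpoint in k1 and smallest in k2
  mid1 <- (p1[, 1L] + p1[c(2:n1, 1L), 1L]) / 2
  mid2 <- (p2[, 1L] + p2[c(2:n2, 1L), 1L]) / 2
  e1 <- which.max(mid1)     # edge p1[e1] -> p1[e1+1]
  e2 <- which.min(mid2)
  rot_from <- function(e, n) if (e == n) seq_len(n)
                             else c(seq(e + 1L, n), seq_len(e))
  ord1 <- rot_from(e1, n1)                 # starts at head of cut edge
  ord2 <- rot_from(e2, n2)
  # traversal: ... -> p1[e1] -> p2[e2+1] -> ... -> p2[e2] -> p1[e1+1] -> ...
  pts <- rbind(p1[ord1, , drop = FALSE], p2[ord2, , drop = FALSE])
  build_link(pts, closed = TRUE)
}

#' @param l1,l2 arbitrary `polygonal_link`s.
#' @rdname connected_sum
#' @export
split_union <- function(l1, l2) {
  p1 <- l1$points; p2 <- l2$points
  shift <- max(p1[, 1L]) - min(p2[, 1L]) + 4 +
    0.5 * (bbox_diag(p1) + bbox_diag(p2))
  p2[, 1L] <- p2[, 1L] + shift
  build_link(rbind(p1, p2),
             sep = c(l1$sep, nrow(p1) + l2$sep),
             closed = c(l1$closed, l2$closed))
}

#' Build a fixture from a specification
#'
#' Dispatch front end over the individual fixture constructors; the
#' same specification always yields bit-identical coordinates.
#'
#' @param what the fixture kind: one of `"torus_knot"`, `"figure_eight"`, `"twist_knot"`,
#'   `"hopf"`, `"unlink"`, `"random_chain"`, `"stick_trefoil"`,
#'   `"stick_figure_eight"`.
#' @param n_points sample count where applicable.
#' @param seed seed for `random_chain`.
#' @param ... kind-specific arguments (`p`, `q`, `k`, `sign`, `style`);
#'   must be named exactly.
#' @return a `polygonal_link`.
#' @export
make_fixture <- function(what, ..., n_points = NULL, seed = 1L) {
  args <- list(...)
  switch(what,
    torus_knot = fixture_torus_knot(p = args$p %||% 2L, q = args$q %||% 3L,
                                    n = n_points %||% 60L),
    figure_eight = fixture_figure_eight(n = n_points %||% 100L),
    twist_knot = fixture_twist_knot(args$k %||% 1L),
    hopf = fixture_hopf(sign = args$sign %||% 1L),
    unlink = fixture_unlink(k = args$k %||% 2L),
    random_chain = random_chain(n = n_points %||% 50L, seed = seed,
                                style = args$style %||% "walk"),
    stick_trefoil = fixture_stick_trefoil(),
    stick_figure_eight = fixture_stick_figure_eight(),
    stop("unknown fixture kind: ", what)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
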