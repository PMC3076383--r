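# shared test fixtures and small independent oracles

# seeded rigid rotation, independent of package internals
test_rotation <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

rotated_copy <- function(link, seed) {
  out <- link
  out$points <- link$points %*% t(test_rotation(seed))
  out
}

# independent brute-force projected-crossing counter: plain double loop,
# no shared code with find_crossings
brute_crossings <- function(link) {
  ed <- link_edges(link)
  P <- link$points
  hits <- 0L
  signs <- integer(0)
  ne <- nrow(ed)
  for (i in seq_len(ne - 1L)) for (j in seq(i + 1L, ne)) {
    shared <- length(intersect(ed[i, 1:2], ed[j, 1:2])) > 0L
    if (shared) next
    p1 <- P[ed[i, 1L], ]; p2 <- P[ed[i, 2L], ]
    q1 <- P[ed[j, 1L], ]; q2 <- P[ed[j, 2L], ]
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) next
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    if (t <= 0 || t >= 1 || u <= 0 || u >= 1) next
    hits <- hits + 1L
    zi <- p1[3] + t * d1[3]; zj <- q1[3] + u * d2[3]
    dov <- if (zi > zj) d1 else d2
    dun <- if (zi > zj) d2 else d1
    signs <- c(signs, if (dov[1] * dun[2] - dov[2] * dun[1] > 0) 1L else -1L)
  }
  list(n = hits, signs = signs)
}

# deep synthetic open trefoil: parametric trefoil opened at one vertex
# with straight tails appended at both ends
deep_trefoil_chain <- function(n_tail = 15L, n_knot = 36L) {
  tr <- fixture_torus_knot(2L, 3L, n_knot)$points
  n <- nrow(tr)
  d1 <- tr[1, ] - tr[2, ]; d1 <- d1 / sqrt(sum(d1^2))
  d2 <- tr[n, ] - tr[n - 1, ]; d2 <- d2 / sqrt(sum(d2^2))
  head_tail <- t(sapply(seq_len(n_tail), function(k) tr[1, ] + k * 0.9 * d1))
  tail_tail <- t(sapply(seq_len(n_tail), function(k) tr[n, ] + k * 0.9 * d2))
  build_link(rbind(head_tail[n_tail:1, , drop = FALSE], tr, tail_tail),
             closed = FALSE)
}

# shallow trefoil: opened right at the knot, tiny tails
shallow_trefoil_chain <- function() {
  tr <- fixture_torus_knot(2L, 3L, 36L)$points
  n <- nrow(tr)
  d2 <- tr[n, ] - tr[n - 1, ]; d2 <- d2 / sqrt(sum(d2^2))
  tails <- t(sapply(1:2, function(k) tr[n, ] + k * 0.9 * d2))
  build_link(rbind(tr, tails), closed = FALSE)
}

# synthetic PDB text: one ATOM line per residue from a coordinate matrix
pdb_atom_line <- function(serial, resno, xyz, chain = "A", atom = "CA") {
  sprintf("ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, atom, chain, resno, xyz[1], xyz[2], xyz[3])
}

synthetic_pdb <- function(coords, chain = "A", start_res = 1L,
                          header = TRUE) {
  lines <- if (header) "HEADER    SYNTHETIC FIXTURE                       01-JAN-11   TEST" else character(0)
  for (i in seq_len(nrow(coords)))
    lines <- c(lines, pdb_atom_line(i, start_res + i - 1L, coords[i, ],
                                    chain = chain))
  c(lines, "END")
}

# protein-like helix chain, unknotted by construction for these seeds
helix_chain <- function(n = 120L, seed = 7L) random_chain(n, seed, "helix_mix")

# the full closed-link validation battery (name -> link)
battery_links <- function() {
  list(
    unknot   = fixture_unlink(1L),
    tre_R    = fixture_torus_knot(2L, 3L, 36L),
    tre_L    = mirror_link(fixture_torus_knot(2L, 3L, 36L)),
    fig8     = fixture_figure_eight(60L),
    k5_1     = fixture_torus_knot(2L, 5L, 60L),
    k5_2     = fixture_twist_knot(3L),
    k6_1     = fixture_twist_knot(4L),
    hopf_p   = fixture_hopf(1L),
    hopf_m   = fixture_hopf(-1L),
    unlink2  = fixture_unlink(2L),
    unlink3  = fixture_unlink(3L))
}
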