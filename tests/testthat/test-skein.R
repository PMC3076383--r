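# independent side-vs-edges dirt test used to re-verify Xclean results
brute_side_dirty <- function(link, excl, p, q) {
  ed <- link_edges(link)
  P <- link$points
  for (i in setdiff(seq_len(nrow(ed)), excl)) {
    a <- P[ed[i, 1], 1:2]; b <- P[ed[i, 2], 1:2]
    d1 <- q - p; d2 <- b - a
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) next
    t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / den
    u <- ((a[1] - p[1]) * d1[2] - (a[2] - p[2]) * d1[1]) / den
    if (t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9)
      return(TRUE)
  }
  FALSE
}

test_that("clean quadrilaterals are found and verified by brute force", {
  f8 <- fixture_figure_eight(60)
  cr <- find_crossings(f8)
  for (i in seq_len(nrow(cr))) {
    q <- build_clean_quadrilateral(f8, cr[i, ])
    expect_s3_class(q, "skein_quad")
    expect_true(all(q$t > 0))
    poly <- q$v3[q$order, 1:2, drop = FALSE]
    excl <- c(q$ctx$eo, q$ctx$eu)
    for (s in 1:4)
      expect_false(brute_side_dirty(f8, excl, poly[s, ],
                                    poly[s %% 4 + 1, ]))
  }
})

test_that("an isolated crossing accepts the full cut edges", {
  # two skew segments crossing once, nothing else in the diagram
  l <- build_link(rbind(c(-1, 0, 0), c(1, 0, 0),
                        c(0, -1, 1), c(0, 1, 1)),
                  sep = c(1L, 3L), closed = c(FALSE, FALSE))
  cr <- find_crossings(l)
  q <- build_clean_quadrilateral(l, cr[1, ])
  expect_identical(q$t, rep(1, 4))
})

test_that("xclean incremental updates equal full recomputation", {
  f8 <- fixture_figure_eight(60)
  cr <- find_crossings(f8)
  q <- build_clean_quadrilateral(f8, cr[1, ])
  poly <- q$v3[q$order, 1:2, drop = FALSE]
  excl <- c(q$ctx$eo, q$ctx$eu)
  full <- xclean(poly, f8, exclude_edges = excl)
  # grow the polygon at one vertex, update incrementally
  poly2 <- poly
  poly2[2, ] <- poly[2, ] + (poly[2, ] - colMeans(poly)) * 3
  inc <- xclean(poly2, f8, status = full$status, touched = 2L,
                exclude_edges = excl)
  ref <- xclean(poly2, f8, exclude_edges = excl)
  expect_identical(inc$status, ref$status)
  expect_identical(inc$clean, ref$clean)
})

test_that("rotated quadrilaterals avoid parallel sides and stay clean", {
  f8 <- fixture_figure_eight(60)
  cr <- find_crossings(f8)
  for (i in seq_len(nrow(cr))) {
    q <- build_clean_quadrilateral(f8, cr[i, ])
    rr <- rotate_quadrilateral(f8, q, cr[i, ])
    expect_gt(rr$theta, 1e-12)
    poly <- rr$quad_rot$v3r[q$order, 1:2, drop = FALSE]
    excl <- c(q$ctx$eo, q$ctx$eu)
    for (s in 1:4)
      expect_false(brute_side_dirty(f8, excl, poly[s, ],
                                    poly[s %% 4 + 1, ]))
    # no side parallel to either crossing edge
    ed <- link_edges(f8); P <- f8$points
    for (e in excl) {
      d <- P[ed[e, 2], 1:2] - P[ed[e, 1], 1:2]
      for (s in 1:4) {
        sv <- poly[s %% 4 + 1, ] - poly[s, ]
        expect_gt(abs(sv[1] * d[2] - sv[2] * d[1]),
                  1e-9 * sqrt(sum(sv^2)) * sqrt(sum(d^2)))
      }
    }
  }
})

test_that("two_side_replacement_check accepts clean and rejects dirty", {
  l <- build_link(rbind(c(-2, 0, 0), c(2, 0, 0),
                        c(0, -2, 1), c(0, 2, 1),
                        c(5, -1, 0), c(5, 1, 0)),
                  sep = c(1L, 3L, 5L), closed = c(FALSE, FALSE, FALSE))
  # original path crosses the y-axis strand once, passing under it
  orig <- rbind(c(-2, 0, 0), c(0.3, 0.5, 0), c(2, 0, 0))
  repl_clean <- rbind(c(-2, 0, 0), c(0.4, 0.6, 0), c(2, 0, 0))
  expect_true(two_side_replacement_check(l, orig, repl_clean,
                                         exclude_edges = 1L))
  # replacement wandering across the distant third component
  repl_dirty <- rbind(c(-2, 0, 0), c(6, 0, 0.5), c(2, 0, 0))
  expect_false(two_side_replacement_check(l, orig, repl_dirty,
                                          exclude_edges = 1L))
  # replacement crossing the same strand with the opposite status
  repl_flip <- rbind(c(-2, 0, 0), c(0.3, 0.5, 3), c(2, 0, 0))
  expect_false(two_side_replacement_check(l, orig, repl_flip,
                                          exclude_edges = 1L))
  # dirty dividing segment
  expect_false(two_side_replacement_check(
    l, orig, repl_clean,
    dividing_segment = rbind(c(4.5, 0, 0), c(5.5, 0, 0)),
    exclude_edges = 1L))
})

test_that("switching a trefoil crossing unknots it (and is an involution)", {
  # minimal 3-crossing diagram: any switch unknots the trefoil
  tr <- fixture_braid(c(1, 1, 1))
  cr <- find_crossings(tr)
  expect_identical(nrow(cr), 3L)
  skein_audit_enable(TRUE); skein_audit_reset()
  for (i in seq_len(nrow(cr))) {
    sw <- make_switch_config(tr, cr[i, ])
    expect_true(l2_equal(homfly_from_diagram(gauss_code(sw)), l2_one()))
  }
  log <- skein_audit_log()
  skein_audit_enable(FALSE)
  expect_identical(nrow(log), 3L)
  expect_true(all(log$alpha_start == 0.9))
  expect_true(all(log$alpha_final >= 0.9 & log$alpha_final < 1))
  expect_true(all(log$changed_crossings == 1L))
  expect_true(all(log$overpass))
  # switching the same crossing twice returns to the original class
  sw1 <- make_switch_config(tr, cr[1, ])
  cr1 <- find_crossings(sw1)
  tgt <- which(cr1$sign == -cr$sign[1])  # the switched crossing
  sw2 <- make_switch_config(sw1, cr1[tgt[1], ])
  expect_true(l2_equal(homfly_from_diagram(gauss_code(sw2)),
                       homfly_from_diagram(gauss_code(tr))))
  # on a non-minimal diagram the switch agrees with the abstract
  # Gauss-code switch of the same crossing
  tr6 <- msr_reduce(fixture_torus_knot(2, 3, 36))$link
  cr6 <- find_crossings(tr6)
  for (i in seq_len(nrow(cr6))) {
    geo <- homfly_from_diagram(gauss_code(make_switch_config(tr6, cr6[i, ])))
    abs_sw <- homfly_from_diagram(skeinpath:::gc_switch(gauss_code(tr6), i))
    expect_true(l2_equal(geo, abs_sw))
  }
})

test_that("oriented smoothing adjusts component counts and knot types", {
  tr <- fixture_braid(c(1, 1, 1))   # minimal 3-crossing diagram
  cr <- find_crossings(tr)
  z <- make_zero_config(tr, cr[1, ])
  expect_identical(link_ncomp(z), 2L)       # self-crossing splits
  # smoothing a trefoil crossing yields a Hopf link
  pz <- homfly_from_diagram(gauss_code(z))
  expect_identical(identify_knot(pz)$name, "Hopf+")
  h <- msr_reduce(fixture_hopf(1))$link
  crh <- find_crossings(h)
  zh <- make_zero_config(h, crh[1, ])
  expect_identical(link_ncomp(zh), 1L)      # two components merge
})

test_that("crossing selection strategies obey their contracts", {
  sq <- build_link(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0), closed = TRUE)
  expect_null(select_crossing(sq, "fixed"))
  expect_null(select_crossing(sq, "greedy"))
  tr <- fixture_braid(c(1, 1, 1))
  for (strat in c("greedy", "fixed")) {
    sel <- select_crossing(tr, strat)
    expect_false(is.null(sel))
    sw <- if (!is.null(sel$switched)) sel$switched
          else msr_reduce(make_switch_config(tr, sel$crossing))$link
    expect_true(l2_equal(homfly_from_diagram(gauss_code(
      ensure_general_position(sw, 2))), l2_one()))
  }
  # determinism of selection
  s1 <- select_crossing(tr, "greedy"); s2 <- select_crossing(tr, "greedy")
  expect_identical(s1$crossing, s2$crossing)
})

test_that("skein trees have the expected shape and weights", {
  sq <- build_link(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0), closed = TRUE)
  t0 <- build_skein_tree(sq)
  expect_identical(t0$g, 0L); expect_identical(t0$nu, 1L)
  expect_true(l2_equal(propagate_weights(t0), l2_one()))
  tt <- build_skein_tree(fixture_stick_trefoil())
  expect_identical(tt$nu, 5L)
  expect_identical(tt$g, 2L)
  expect_identical(l2_format(propagate_weights(tt)),
                   "1*l^-2*m^2 - 2*l^-2 - 1*l^-4")
  # greedy and fixed agree on the polynomial
  f8 <- fixture_figure_eight(60)
  pg <- propagate_weights(build_skein_tree(f8, "greedy"))
  pf <- propagate_weights(build_skein_tree(f8, "fixed"))
  expect_true(l2_equal(pg, pf))
})

test_that("skein identities hold at every inner node (oracle check)", {
  for (l in list(fixture_stick_trefoil(), fixture_hopf(-1))) {
    tree <- build_skein_tree(l)
    v <- verify_skein_identities(tree)
    expect_gt(nrow(v), 0L)
    expect_true(all(v$identity_ok))
    expect_true(all(v$epsilon %in% c(-1L, 1L)))
  }
})

test_that("skein tree JSON export is parseable and complete", {
  tree <- build_skein_tree(fixture_stick_trefoil())
  path <- tempfile(fileext = ".json")
  skein_tree_json(tree, path)
  j <- jsonlite::read_json(path)
  expect_identical(j$nu, length(j$nodes))
  expect_identical(j$strategy, "greedy")
  unlink(path)
})
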