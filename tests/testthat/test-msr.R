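test_that("grm_conditions classifies the textbook cases", {
  # straight planar chain: all status sets empty -> admissible
  zz <- build_link(cbind(0:9, rep(c(0, 1), 5), 0), closed = FALSE)
  M <- intersection_matrix(zz)
  cc <- grm_conditions(zz, M, list(comp = 1L, i_s = 1L, i_f = 10L))
  expect_true(cc$ok)
  expect_true(is.na(cc$which_failed))
  # subpath crossing another component once over and once under -> C2
  over_under <- build_link(rbind(
    c(0, 0, 0), c(1, 0, 1), c(2, 0, -1), c(3, 0, 0),       # weaving arc
    c(0.8, -1, 0), c(0.8, 1, 0), c(2.2, 1, 0), c(2.2, -1, 0)),
    sep = c(1L, 5L), closed = c(FALSE, FALSE))
  M2 <- intersection_matrix(over_under)
  cc2 <- grm_conditions(over_under, M2, list(comp = 1L, i_s = 1L, i_f = 4L))
  expect_false(cc2$ok)
  expect_identical(cc2$which_failed, "C2")
})

test_that("a planar zig-zag collapses in one maximal move", {
  zz <- build_link(cbind(0:9, rep(c(0, 1), 5), 0), closed = FALSE)
  M <- intersection_matrix(zz)
  r <- grm(zz, M, 1L)
  expect_true(r$accepted)
  expect_identical(r$move$i_f, 10L)
  expect_identical(r$move$length, 7L)
  expect_identical(nrow(r$link$points), 2L)
})

test_that("the 6-stick trefoil admits no move from any start", {
  st <- ensure_general_position(fixture_stick_trefoil(), 1)
  M <- intersection_matrix(st)
  for (i in 1:6) {
    r <- grm(st, M, i)
    expect_false(r$accepted)
  }
  # and msr_reduce leaves it at the stick bound
  red <- msr_reduce(st)
  expect_identical(nrow(red$link$points), 6L)
})

test_that("incrementally updated matrices equal full recomputation", {
  for (s in 1:6) {
    link <- ensure_general_position(random_chain(25, s), seed = s)
    M <- intersection_matrix(link)
    i <- 1L
    while (i <= nrow(link$points)) {
      r <- grm(link, M, i)
      if (!r$accepted) { i <- i + 1L; next }
      link <- r$link; M <- r$matrix
      expect_identical(M, unname(intersection_matrix(link)))
    }
  }
})

test_that("msr_reduce collapses unknotted chains and respects limits", {
  rc <- random_chain(100, seed = 3)
  # unknottedness certified by the oracle on the closed unreduced chain
  red <- msr_reduce(rc)
  expect_identical(nrow(red$link$points), 2L)
  expect_true(all(diff(red$trace$residual_points) < 0))
  # iteration_limit 0 is the identity
  r0 <- msr_reduce(rc, iteration_limit = 0L)
  expect_identical(r0$link$points, rc$points)
  expect_identical(nrow(r0$trace), 0L)
})

test_that("reduction preserves the HOMFLY polynomial of the trefoil", {
  tr <- fixture_torus_knot(2, 3, 60)
  before <- homfly_from_diagram(gauss_code(tr))
  red <- msr_reduce(tr)
  expect_gte(nrow(red$link$points), 6L)   # stick number floor
  after <- homfly_from_diagram(gauss_code(
    ensure_general_position(red$link, 2)))
  expect_true(l2_equal(before, after))
})

test_that("minimality is a fixpoint", {
  for (l in list(fixture_torus_knot(2, 3, 36), random_chain(40, 5))) {
    r1 <- msr_reduce(l)
    r2 <- msr_reduce(r1$link)
    expect_identical(r2$link$points, r1$link$points)
    expect_identical(nrow(r2$trace), 0L)
  }
})

test_that("move_stats summarises traces", {
  tr <- data.frame(step = 1:3, residual_points = c(20L, 15L, 9L),
                   move_length = c(0L, 0L, 4L), component = 1L,
                   i_s = 1L, i_f = 3L)
  st <- move_stats(list(tr))
  expect_equal(st$zero_fraction, 2 / 3)
  expect_equal(st$quartiles,
               unname(quantile(c(0, 0, 4), c(.25, .5, .75))))
  expect_identical(nrow(st$pairs), 3L)
  # planar single-collapse chains have no zero-length moves
  zz <- build_link(cbind(0:9, rep(c(0, 1), 5), 0), closed = FALSE)
  st2 <- move_stats(list(msr_reduce(zz)$trace))
  expect_identical(st2$zero_fraction, 0)
  expect_error(move_stats(list()), "at least one")
})

test_that("random chain batches produce deterministic statistics", {
  traces <- lapply(1:20, function(s) msr_reduce(random_chain(30, s))$trace)
  st <- move_stats(traces)
  expect_gt(st$n_moves, 0L)
  traces2 <- lapply(1:20, function(s) msr_reduce(random_chain(30, s))$trace)
  expect_identical(move_stats(traces2)$mean, st$mean)
})

test_that("trace TSV export is well-formed", {
  red <- msr_reduce(random_chain(30, 1))
  path <- tempfile(fileext = ".tsv")
  write_trace_tsv(red$trace, path)
  back <- read.delim(path)
  expect_identical(nrow(back), nrow(red$trace))
  expect_identical(names(back),
                   c("step", "residual_points", "move_length",
                     "component", "i_s", "i_f"))
  unlink(path)
})
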