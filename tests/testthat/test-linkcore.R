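square <- function(z = 0) cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), z)

test_that("build_link validates structure and simplicity", {
  l <- build_link(square(), closed = TRUE)
  expect_s3_class(l, "polygonal_link")
  expect_identical(nrow(link_edges(l)), 4L)
  # two separated unit squares -> 2 components with separators 1, 5
  l2 <- build_link(rbind(square(), square() + 3), sep = c(1L, 5L),
                   closed = TRUE)
  expect_identical(length(l2$sep), 2L)
  # duplicated middle point: zero-length edge
  expect_error(build_link(cbind(c(0, 1, 1, 2), 0, 0), closed = FALSE),
               "zero-length")
  # crossing segments in 3D: not simple
  xpts <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, -1, 0), c(1, 1, 0))
  expect_error(build_link(xpts, sep = c(1L, 3L), closed = FALSE),
               class = "skeinpath_nonsimple")
  expect_error(build_link(square()[1:1, , drop = FALSE]), "at least 2")
})

test_that("find_crossings matches a brute-force oracle on fixtures", {
  expect_identical(nrow(find_crossings(build_link(square(), closed = TRUE))),
                   0L)
  tr <- fixture_torus_knot(2, 3, 60)
  cr <- find_crossings(tr)
  bf <- brute_crossings(tr)
  expect_identical(nrow(cr), 3L)
  expect_identical(bf$n, 3L)
  expect_true(all(cr$sign == cr$sign[1]))
  expect_identical(sort(cr$sign), sort(bf$signs))
  f8 <- fixture_figure_eight(100)
  cf <- find_crossings(f8)
  bf8 <- brute_crossings(f8)
  expect_identical(nrow(cf), 4L)
  expect_identical(bf8$n, 4L)
  expect_identical(sum(cf$sign), 0L)
})

test_that("non-regular projections are refused with guidance", {
  # vertical segment pair projecting onto each other
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))
  l <- build_link(pts, closed = TRUE)
  expect_error(find_crossings(l), class = "skeinpath_nonregular")
  g <- ensure_general_position(l, seed = 3)
  expect_true(isTRUE(is_regular(g)))
})

test_that("ensure_general_position is idempotent and deterministic", {
  tr <- fixture_torus_knot(2, 3, 36)
  expect_identical(ensure_general_position(tr, 1)$points, tr$points)
  bad <- build_link(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
                    closed = TRUE)
  g1 <- ensure_general_position(bad, seed = 5)
  g2 <- ensure_general_position(bad, seed = 5)
  expect_identical(g1$points, g2$points)
})

test_that("mirroring swaps over/under and negates signs crossing-by-crossing", {
  tr <- fixture_torus_knot(2, 3, 36)
  cr <- find_crossings(tr)
  cm <- find_crossings(mirror_link(tr))
  expect_identical(cm$over_edge, cr$under_edge)
  expect_identical(cm$under_edge, cr$over_edge)
  expect_identical(cm$sign, -cr$sign)
  back <- mirror_link(mirror_link(tr))
  expect_identical(find_crossings(back), cr)
  expect_identical(nrow(find_crossings(mirror_link(
    build_link(square(), closed = TRUE)))), 0L)
})

test_that("intersection matrix is antisymmetric and counts crossings", {
  sq <- build_link(square(), closed = TRUE)
  expect_true(all(intersection_matrix(sq) == 0L))
  tr <- fixture_torus_knot(2, 3, 36)
  M <- intersection_matrix(tr)
  expect_identical(sum(M != 0L), 6L)
  expect_identical(M, -t(M))
  h <- fixture_hopf(1)
  ed <- link_edges(h)
  E <- which(ed[, 3] == 1L); F <- which(ed[, 3] == 2L)
  Mh <- intersection_matrix(h, E, F)
  expect_identical(sum(Mh != 0L), 2L)
})

test_that("crossing signs match the brute-force oracle on rotated copies", {
  # general positioning of an already-regular link is the identity, so
  # the sign sum (diagram writhe) is trivially preserved there; rotated
  # copies get a different diagram whose signs must still match the
  # independent brute-force computation
  tr <- fixture_torus_knot(2, 3, 36)
  expect_identical(ensure_general_position(tr, 9)$points, tr$points)
  for (s in 1:5) {
    g <- ensure_general_position(rotated_copy(tr, s), seed = s)
    cr <- find_crossings(g)
    bf <- brute_crossings(g)
    expect_identical(nrow(cr), bf$n)
    expect_identical(sort(cr$sign), sort(bf$signs))
  }
})

test_that("coordinate files round-trip to 12 significant digits", {
  l <- split_union(fixture_torus_knot(2, 3, 36),
                   build_link(square(), closed = FALSE))
  path <- tempfile(fileext = ".xyz")
  write_link_file(l, path)
  l2 <- read_link_file(path)
  expect_identical(l2$sep, l$sep)
  expect_identical(l2$closed, l$closed)
  expect_equal(unname(l2$points), unname(l$points), tolerance = 1e-11)
  unlink(path)
})
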