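test_that("the geometric pipeline reproduces unknots and trefoils", {
  sq <- build_link(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0), closed = TRUE)
  expect_true(l2_equal(homfly(sq), l2_one()))
  pr <- homfly(fixture_torus_knot(2, 3, 36))
  pl <- homfly(mirror_link(fixture_torus_knot(2, 3, 36)))
  expect_false(l2_equal(pr, pl))
  expect_true(l2_equal(pl, l2_mirror(pr)))
  expect_identical(identify_knot(pr)$handedness, "R")
  expect_identical(identify_knot(pl)$handedness, "L")
})

test_that("chirality: Alexander is blind where Jones discriminates", {
  pr <- homfly(fixture_torus_knot(2, 3, 36))
  pl <- l2_mirror(pr)
  ar <- specialize(pr, "alexander"); al <- specialize(pl, "alexander")
  expect_true(skeinpath:::l1h_equal(ar, al))
  jr <- specialize(pr, "jones"); jl <- specialize(pl, "jones")
  expect_false(skeinpath:::l1h_equal(jr, jl))
})

test_that("the figure-eight is amphichiral through the pipeline", {
  f8 <- fixture_figure_eight(60)
  p <- homfly(f8)
  pm <- homfly(mirror_link(f8))
  expect_true(l2_equal(p, pm))
  expect_true(l2_equal(p, l2_mirror(p)))
  j <- specialize(p, "jones")
  expect_identical(j$coef, rev(j$coef))   # palindromic under t <-> 1/t
})

test_that("pipeline equals the diagrammatic oracle on mixed fixtures", {
  for (l in list(fixture_twist_knot(3), fixture_hopf(-1),
                 fixture_stick_figure_eight())) {
    expect_true(l2_equal(
      homfly(l),
      homfly_from_diagram(gauss_code(ensure_general_position(l, 1)))))
  }
})

test_that("multiplicativity under connected sum and split union", {
  tr <- fixture_torus_knot(2, 3, 36)
  p3 <- homfly(tr)
  granny <- connected_sum(tr, tr)
  expect_true(l2_equal(homfly(granny), l2_mul(p3, p3)))
  square_knot <- connected_sum(tr, mirror_link(tr))
  ps <- homfly(square_knot)
  expect_true(l2_equal(ps, l2_mul(p3, l2_mirror(p3))))
  expect_true(l2_equal(ps, l2_mirror(ps)))    # symmetric under l <-> 1/l
  un <- build_link(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0), closed = TRUE)
  expect_true(l2_equal(homfly(split_union(un, un)), unlink_poly(2)))
})

test_that("identify_knot matches the table and echoes unknowns", {
  expect_identical(identify_knot(l2_one())$name, "U")
  id <- identify_knot(homfly(fixture_torus_knot(2, 3, 36)))
  expect_identical(id$name, "3_1")
  expect_identical(id$handedness, "R")
  odd <- l2_poly(7L, 3L, 5)
  u <- identify_knot(odd)
  expect_identical(u$name, "unidentified")
  expect_identical(u$polynomial, l2_format(odd))
})

test_that("the knot table is internally consistent", {
  tab <- knot_table()
  # mirror pairs related by l <-> 1/l
  for (nm in c("3_1", "5_1", "5_2", "6_1")) {
    rows <- tab[tab$name == nm, ]
    expect_identical(nrow(rows), 2L)
    p <- l2_parse(rows$polynomial[rows$handedness == "R"])
    q <- l2_parse(rows$polynomial[rows$handedness == "L"])
    expect_true(l2_equal(q, l2_mirror(p)))
  }
  achiral <- tab[tab$name == "4_1", ]
  p <- l2_parse(achiral$polynomial)
  expect_true(l2_equal(p, l2_mirror(p)))
})

test_that("homfly is invariant under flip variants of a knot", {
  tr <- fixture_torus_knot(2, 3, 36)
  p <- homfly(tr)
  expect_true(l2_equal(homfly(reverse_link(tr)), p))
  expect_true(l2_equal(homfly(reverse_link(mirror_link(tr))),
                       l2_mirror(p)))
})

test_that("the shipped knot table TSV matches a regeneration", {
  shipped <- system.file("extdata", "knot_table.tsv", package = "skeinpath")
  expect_true(nzchar(shipped))
  path <- tempfile(fileext = ".tsv")
  write_knot_table(path)
  expect_identical(readLines(path), readLines(shipped))
  unlink(path)
})
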