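test_that("read_backbone parses crafted PDB fixtures", {
  coords <- cbind(3.8 * (0:4), 0, 0)
  txt <- synthetic_pdb(coords)
  ch <- read_backbone(txt)
  expect_identical(length(ch), 1L)
  expect_identical(nrow(ch[[1]]$residues), 5L)
  expect_identical(ch[[1]]$chain_id, "A")
  # two MODEL blocks: only the first is used
  txt2 <- c("MODEL        1", synthetic_pdb(coords, header = FALSE)[1:5],
            "ENDMDL", "MODEL        2",
            synthetic_pdb(coords + 100, header = FALSE)[1:5], "ENDMDL",
            "END")
  ch2 <- read_backbone(txt2)
  expect_identical(nrow(ch2[[1]]$residues), 5L)
  expect_equal(ch2[[1]]$residues$x[1], 0)
  # altloc A and B on one residue: exactly one CA kept
  al <- sub("^(ATOM  .{10})\\s", "\\1A", synthetic_pdb(coords)[3])
  bl <- sub("^(ATOM  .{10})\\s", "\\1B", synthetic_pdb(coords)[3])
  txt3 <- c(synthetic_pdb(coords)[1:2], al, bl, synthetic_pdb(coords)[4:7])
  ch3 <- read_backbone(txt3)
  expect_identical(nrow(ch3[[1]]$residues), 5L)
  # short chains are skipped with a message, empty result is not an error
  expect_message(out <- read_backbone(synthetic_pdb(coords[1:3, ])),
                 "fewer than 4")
  expect_identical(length(out), 0L)
  # malformed ATOM coordinates raise a structured error
  bad <- synthetic_pdb(coords)
  substr(bad[3], 31, 38) <- "   xx.xx"
  expect_error(read_backbone(bad), "unparseable ATOM record at line 3")
})

test_that("split_parts cuts at gaps and drops fragments", {
  # distances 3.8, 3.8, 12.0, 3.8, 3.8 -> two parts of 3 residues are
  # dropped; build longer flanks so both parts survive
  xs <- c(3.8 * (0:4), 3.8 * 4 + 12 + 3.8 * (0:4))
  chain <- list(pdb_id = "synt", chain_id = "A",
                residues = data.frame(resno = seq_along(xs), x = xs,
                                      y = 0, z = 0))
  parts <- split_parts(chain)
  expect_identical(length(parts), 2L)
  expect_identical(nrow(parts[[1]]$link$points), 5L)
  expect_false(parts[[1]]$link$closed[1])
  # gap-free chain: one part spanning everything
  chain2 <- list(pdb_id = "synt", chain_id = "A",
                 residues = data.frame(resno = 1:6, x = 3.8 * (0:5),
                                       y = 0, z = 0))
  expect_identical(length(split_parts(chain2)), 1L)
})

test_that("parts count is non-decreasing as the threshold decreases", {
  # chains with seeded gaps of graded sizes: lowering the threshold can
  # only split more (every part long enough to survive the length
  # filter by construction)
  for (s in 1:5) {
    set.seed(100 + s)
    gap_sizes <- sample(c(5, 8, 12), 3)
    xs <- c(3.8 * (0:9),
            3.8 * 9 + gap_sizes[1] + 3.8 * (0:9),
            3.8 * 18 + gap_sizes[1] + gap_sizes[2] + 3.8 * (0:9),
            3.8 * 27 + sum(gap_sizes) + 3.8 * (0:9))
    chain <- list(pdb_id = "x", chain_id = "A",
                  residues = data.frame(resno = seq_along(xs), x = xs,
                                        y = 0, z = 0))
    counts <- vapply(c(15, 10, 6, 4.5),
                     function(th) length(split_parts(chain, th)), 1L)
    expect_true(all(diff(counts) >= 0L))
    expect_identical(counts[4], 4L)
  }
})

test_that("closure classifies unknotted and deeply knotted chains", {
  hx <- helix_chain(100, seed = 7)
  cl <- close_and_classify(hx)
  expect_identical(cl$record$name, "U")
  expect_identical(l2_format(cl$polynomial), "1")
  dt <- deep_trefoil_chain()
  for (pol in c("direct", "radial")) {
    cd <- close_and_classify(dt, closure = pol)
    expect_identical(cd$record$name, "3_1")
    expect_identical(cd$record$handedness, "R")
  }
})

test_that("knotted cores are deep for deep knots, shallow for shallow", {
  dt <- deep_trefoil_chain()
  core <- knotted_core(list(link = dt))
  expect_gt(core$n_trim, 10L)
  expect_gt(core$c_trim, 10L)
  expect_identical(core$knot$name, "3_1")
  # applying the reported trims unknots the part
  n <- nrow(dt$points)
  sub <- build_link(dt$points[(core$n_trim + 1):(n - core$c_trim), ],
                    closed = FALSE)
  expect_identical(close_and_classify(sub)$record$name, "U")
  sh <- shallow_trefoil_chain()
  core_sh <- knotted_core(list(link = sh))
  expect_lte(min(core_sh$n_trim, core_sh$c_trim), 5L)
  # unknotted parts cannot be cored
  expect_error(knotted_core(list(link = helix_chain(60, 3))),
               "nothing to core")
})

test_that("gap splitting prevents artificial entanglement", {
  # a knotted chain with a gap inserted inside the knot: the parts
  # spanning the cut are analysed separately and are unknotted
  dt <- deep_trefoil_chain()$points
  cut <- nrow(dt) %/% 2
  dt[(cut + 1):nrow(dt), ] <- dt[(cut + 1):nrow(dt), ] + 20
  chain <- list(pdb_id = "syn", chain_id = "A",
                residues = data.frame(resno = seq_len(nrow(dt)),
                                      x = dt[, 1], y = dt[, 2], z = dt[, 3]))
  parts <- split_parts(chain)
  expect_identical(length(parts), 2L)
  for (p in parts)
    expect_identical(close_and_classify(p$link)$record$name, "U")
})
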