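test_that("the worked example decomposes into the documented loop types", {
  tgt <- worked_example()
  expect_equal(tgt$n, 28L)
  kinds <- vapply(seq_len(nrow(tgt$pairs)), function(r)
    tgt$loops[[r]]$kind, "")
  got <- stats::setNames(kinds, paste(tgt$pairs[, 1L], tgt$pairs[, 2L]))
  expect_equal(got[["18 23"]], "hairpin")
  expect_equal(tgt$loops[[which(names(got) == "18 23")]]$size, 4L)
  expect_equal(got[["17 24"]], "stack")
  expect_equal(got[["16 26"]], "bulge_right")
  expect_equal(got[["6 10"]], "hairpin")
  expect_equal(got[["5 11"]], "stack")
  expect_equal(got[["3 13"]], "internal")
  expect_equal(got[["2 14"]], "stack")
  expect_equal(got[["1 27"]], "multiloop")
  # constraint forces the tetraloop closing pair to GC only
  r1823 <- which(names(got) == "18 23")
  expect_equal(tgt$allowed_pairs[[r1823]], 3L)   # GC
  # pairs closing the external loop or multiloop
  closers <- names(got)[tgt$bp_close_el_ml]
  expect_setequal(closers, c("1 27", "2 14", "16 26"))
})

test_that("base-pair order ranks inner pairs before their closing pair", {
  tgt <- worked_example()
  bp <- order_base_pairs(tgt)
  rank <- stats::setNames(seq_len(nrow(bp)), paste(bp[, 1L], bp[, 2L]))
  expect_equal(unname(rank[["1 27"]]), 8L)     # outermost pair is last
  for (r in seq_len(nrow(bp))) {
    for (inner in tgt$loops[[r]]$inner)
      expect_lt(inner, r)
  }
  # left sibling helix ranks before the right one
  expect_lt(rank[["2 14"]], rank[["16 26"]])
  expect_lt(rank[["6 10"]], rank[["5 11"]])
  # a lone hairpin pair has rank 1
  one <- parse_target("(....)")
  expect_equal(nrow(one$pairs), 1L)
})

test_that("parser rejects malformed input with distinct errors", {
  expect_error(parse_target("((....)"), "unbalanced")
  expect_error(parse_target("(....))"), "unbalanced")
  expect_error(parse_target("(..)"), "steric")
  expect_error(parse_target("(....)", "NNNNN"), "length")
  expect_error(parse_target("(....)", "NNXNNN"), "IUPAC")
  expect_error(parse_target("(.[.).]"), "characters")
})

test_that("round-trip and position accounting invariants hold", {
  set.seed(5)
  for (q in 1:25) {
    db <- generate_random_structure(sample(5:40, 1L), 0.6, seed = q)
    tgt <- parse_target(db)
    expect_identical(format_dotbracket(tgt), db)
    unpaired <- sum(tgt$pair_table == 0L)
    expect_equal(unpaired + 2L * nrow(tgt$pairs), tgt$n)
  }
  open <- parse_target("....")
  expect_equal(nrow(open$pairs), 0L)
  expect_equal(open$loops[[1L]]$ell, 4L)
})

test_that("IUPAC constraints expand to allowed sets and pair sets", {
  tgt <- parse_target("(((...)))", "NNNGNNNNN")
  expect_equal(tgt$allowed[[4L]], 3L)              # G only
  for (r in 1:3) expect_equal(tgt$allowed_pairs[[r]], 1:6)
  tgt2 <- parse_target("(....)", "YNNNNS")
  # i in {C,U}, j in {C,G}: CG, UG remain
  expect_setequal(tgt2$allowed_pairs[[1L]], c(2L, 6L))
})

test_that("adjacency groups follow the gap-2 rule and are maximal", {
  # two external helices separated by >= 3 unpaired: independent groups
  tgt <- parse_target("(....)...(....)")
  gs <- build_groups(tgt, tgt$loops[[length(tgt$loops)]], "d2")
  expect_length(gs, 2L)
  # helices (2,10), (12,20) in a length-22 external loop: gap 2 merges
  # them, position 11 shared as 3' dangle of one and 5' dangle of the other
  tgt2 <- parse_target(".((.....)).((.....))..")
  g2 <- build_groups(tgt2, tgt2$loops[[length(tgt2$loops)]], "d2")
  expect_length(g2, 1L)
  shared <- g2[[1L]]$dangles
  expect_equal(sum(shared$pos == 11L), 2L)
  expect_true(11L %in% g2[[1L]]$vars)
  # multiloop with both components adjacent to the closing pair: one
  # closing group containing everything
  tgt3 <- worked_example()
  ml <- tgt3$loops[[which(vapply(tgt3$loops, `[[`, "", "kind") == "multiloop")]]
  g3 <- build_groups(tgt3, ml, "d2")
  expect_length(g3, 1L)
  expect_true(g3[[1L]]$closing_member)
  # d0: one degenerate group per helix, no dangle positions
  g0 <- build_groups(tgt3, ml, "d0")
  expect_true(all(lengths(lapply(g0, `[[`, "vars")) == 0L))
  # every helix in exactly one group
  tally <- table(unlist(lapply(g2, `[[`, "pairs")))
  expect_true(all(tally == 1L))
})
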