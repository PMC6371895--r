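test_that("junction codes reproduce the canonical renderings", {
  expect_equal(code_junction(2, c(1, 2))$rendered, "2.12")
  expect_equal(code_junction(2, c(2, 1))$rendered, "2.12")   # order-free
  expect_equal(code_junction(5, c(5, 1, 1))$rendered, "5.511")
  expect_equal(code_junction(5, c(1, 5, 1))$rendered, "5.511")
  expect_equal(code_junction(1, integer(0))$rendered, "1_0")
  expect_equal(code_junction(3, 3)$rendered, "3_0")          # single upstream
  # more than four contributors: largest four retained
  expect_equal(code_junction(5, c(5, 3, 2, 1, 1))$rendered, "5.5321")
  # orders beyond one digit switch to hyphen-joined tokens
  expect_equal(code_junction(12, c(3, 10))$rendered, "12.3-10")
  expect_error(code_junction(0, c(1, 1)), "value error")
  expect_error(code_junction(2, c(0, 1)), "value error")
})

test_that("rendering is injective over retained token sets (orders <= 6, <= 4 tributaries)", {
  keys <- character(0); renders <- character(0)
  for (d in 1:6) {
    multis <- list(integer(0))
    for (size in 2:4) {
      combos <- utils::combn(rep(1:6, size), size)
      multis <- c(multis, unique(apply(combos, 2, sort, simplify = FALSE)))
    }
    for (m in multis) {
      keys <- c(keys, paste(d, paste(sort(m), collapse = ","), sep = "|"))
      renders <- c(renders, code_junction(d, m)$rendered)
    }
  }
  expect_equal(anyDuplicated(keys), 0)
  # distinct (downstream order, multiset) pairs always render distinctly
  expect_equal(length(unique(renders)), length(keys))
})

test_that("non-sensical junction detection matches the Strahler-consistency oracle", {
  for (d in 1:4) for (a in 1:4) for (b in a:4) {
    net <- tiny_net(1:3, c(a, b, d), edges = rbind(c(1, 3), c(2, 3)))
    flagged <- detect_nonsensical_junctions(net)
    m <- max(a, b)
    expected_order <- if (a == b) m + 1L else m
    if (d != expected_order) expect_equal(flagged, 3L)
    else expect_length(flagged, 0)
  }
  # an upstream divergence flag suppresses the flagging
  net <- tiny_net(1:3, c(5, 5, 5), flag = c("main", "secondary", "none"),
                  edges = rbind(c(1, 3), c(2, 3)))
  expect_length(detect_nonsensical_junctions(net), 0)
})

test_that("divergence classes cover D1, D2, DU, D and none", {
  net <- divergence_showcase_net()
  div <- assign_divergence_classes(net)
  expect_equal(unname(div[c("4", "5", "6", "9", "1")]),
               c("D1", "D2", "DU", "D", "none"))
  dend <- generate_dendritic_network(
    generator_config(n_reaches = 100, divergence_rate = 0, split_rate = 0,
                     seed = 2))
  expect_true(all(assign_divergence_classes(dend) == "none"))
})

test_that("bifurcation assignment is total and matches an independent traversal", {
  for (seed in c(3, 14)) {
    net <- generate_dendritic_network(
      generator_config(n_reaches = 200, divergence_rate = 0, split_rate = 0,
                       seed = seed))
    tab <- assign_bifurcation_classes(net)
    expect_equal(nrow(tab), 200)
    expect_true(all(nzchar(tab$bif_class)))
    expect_identical(tab$bif_class,
                     unname(brute_bifurcation_codes(net)))
    # integer part of the code equals the reach's own order
    ints <- as.integer(sub("[._].*$", "", tab$bif_class))
    expect_identical(ints, net$reaches$strahler_order)
  }
})

test_that("split reaches take the class of the upstream-most unit member", {
  # unit of three chained reaches below a 2.11 junction
  net <- tiny_net(1:5, c(1, 1, 2, 2, 2),
                  eco = c(NA, NA, 7L, 7L, 7L),
                  edges = rbind(c(1, 3), c(2, 3), c(3, 4), c(4, 5)))
  cls <- assign_bifurcation_classes(net)
  expect_equal(cls$bif_class[3:5], c("2.11", "2_0", "2_0"))
  fixed <- correct_split_reaches(net, cls)
  expect_equal(fixed$bif_class[3:5], rep("2.11", 3))
  # idempotent
  expect_identical(correct_split_reaches(net, fixed), fixed)
  # singleton unit untouched
  net1 <- tiny_net(1:2, 1, eco = c(5L, NA), edges = rbind(c(1, 2)))
  c1 <- assign_bifurcation_classes(net1)
  expect_identical(correct_split_reaches(net1, c1), c1)
  # disconnected unit skipped with a warning
  net2 <- tiny_net(1:4, 1, eco = c(9L, NA, 9L, NA),
                   edges = rbind(c(1, 2), c(3, 4)))
  c2 <- assign_bifurcation_classes(net2)
  expect_warning(out <- correct_split_reaches(net2, c2), "not a connected")
  expect_identical(out, c2)
})

test_that("split correction preserves unit-head classes on generated networks", {
  net <- generate_dendritic_network(
    generator_config(n_reaches = 300, split_rate = 0.1, seed = 8))
  cls <- assign_bifurcation_classes(net)
  fixed <- correct_split_reaches(net, cls)
  eco <- net$reaches$eco_unit_id
  for (u in unique(eco[!is.na(eco)])) {
    members <- which(eco == u)
    expect_length(unique(fixed$bif_class[members]), 1)
  }
  # reaches outside units are untouched
  loose <- is.na(eco)
  expect_identical(fixed$bif_class[loose], cls$bif_class[loose])
})
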