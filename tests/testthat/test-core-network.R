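test_that("CSV round trip preserves a synthetic network exactly", {
  cfg <- generator_config(n_reaches = 10, seed = 3)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  d <- withr::local_tempdir()
  rp <- file.path(d, "reaches.csv"); fp <- file.path(d, "fromto.csv")
  write_network(net, rp, fp)
  back <- read_network(rp, fp)
  expect_equal(back$reaches$comid, net$reaches$comid)
  expect_equal(back$reaches$mean_annual_q, net$reaches$mean_annual_q)
  expect_equal(back$edges, net$edges)
  # a second write of the re-read network is byte-identical
  rp2 <- file.path(d, "reaches2.csv"); fp2 <- file.path(d, "fromto2.csv")
  write_network(back, rp2, fp2)
  expect_identical(unname(tools::md5sum(rp)), unname(tools::md5sum(rp2)))
  expect_identical(unname(tools::md5sum(fp)), unname(tools::md5sum(fp2)))
})

test_that("reader enforces schema, units and referential integrity", {
  d <- withr::local_tempdir()
  rp <- file.path(d, "r.csv"); fp <- file.path(d, "f.csv")
  writeLines(c("COMID,StreamOrde,LENGTHKM,slope,Q0001A,Divergence,EcoUnitID,InundatedFrac",
               "1,1,1.0,0.01,1.0,none,NA,0"), rp)
  writeLines(c("FROMCOMID,TOCOMID"), fp)
  # declared cfs is converted at ingest
  net <- read_network(rp, fp, list(discharge_unit = "cfs"))
  expect_equal(net$reaches$mean_annual_q, 0.0283168)
  expect_error(read_network(rp, fp, list(discharge_unit = "gallons")),
               "config error")
  # edge to an absent reach
  writeLines(c("FROMCOMID,TOCOMID", "1,99"), fp)
  expect_error(read_network(rp, fp), "integrity error.*99")
  # missing column is named
  writeLines(c("COMID,StreamOrde,LENGTHKM,slope,Divergence,EcoUnitID,InundatedFrac",
               "1,1,1.0,0.01,none,NA,0"), rp)
  writeLines("FROMCOMID,TOCOMID", fp)
  expect_error(read_network(rp, fp), "Q0001A")
})

test_that("constructor rejects duplicate comids and self loops", {
  expect_error(tiny_net(c(1, 1), 1), "duplicate COMID")
  expect_error(tiny_net(1:2, 1, edges = rbind(c(1, 1))), "self-loop")
})

test_that("topology validation reports cycles, orphans and unflagged divergences", {
  chain <- tiny_net(1:3, 1, edges = rbind(c(1, 2), c(2, 3)))
  expect_true(topology_clean(validate_topology(chain)))

  cyc <- tiny_net(1:2, 1, edges = rbind(c(1, 2), c(2, 1)), validate = FALSE)
  rep <- validate_topology(cyc)
  expect_false(topology_clean(rep))
  expect_setequal(rep$cycles, c(1, 2))

  orphan <- tiny_net(1:3, 1, edges = rbind(c(1, 2)))
  expect_equal(validate_topology(orphan)$orphans, 3L)

  split <- tiny_net(1:3, 1, edges = rbind(c(1, 2), c(1, 3)))
  expect_equal(validate_topology(split)$missing_divergence_flags, 1L)
})

test_that("upstream_of returns ordered contributors and errors on unknown ids", {
  junc <- tiny_net(1:3, c(1, 2, 2), edges = rbind(c(2, 3), c(1, 3)))
  expect_identical(upstream_of(junc, 3), c(1L, 2L))
  expect_identical(upstream_of(junc, 1), integer(0))
  threeway <- tiny_net(1:4, c(1, 1, 1, 2),
                       edges = rbind(c(1, 4), c(2, 4), c(3, 4)))
  expect_length(upstream_of(threeway, 4), 3)
  expect_error(upstream_of(junc, 42), "lookup error")
})

test_that("Strahler rule: chains keep order, equal-order junctions increment", {
  chain <- tiny_net(1:3, NA, edges = rbind(c(1, 2), c(2, 3)))
  expect_true(all(compute_strahler_order(chain) == 1L))

  j11 <- tiny_net(1:3, NA, edges = rbind(c(1, 3), c(2, 3)))
  expect_equal(unname(compute_strahler_order(j11)[["3"]]), 2L)

  # two order-1 streams join to order 2; an extra order-1 tributary keeps 2
  net <- tiny_net(1:5, NA,
                  edges = rbind(c(1, 3), c(2, 3), c(3, 5), c(4, 5)))
  o <- compute_strahler_order(net)
  expect_equal(unname(o[["3"]]), 2L)
  expect_equal(unname(o[["5"]]), 2L)   # 1 joining 2 stays 2

  cyc <- tiny_net(1:2, NA, edges = rbind(c(1, 2), c(2, 1)), validate = FALSE)
  expect_error(compute_strahler_order(cyc), "topology error")
})

test_that("accumulation sums upstream and routes 100% down the main channel", {
  chain <- tiny_net(1:3, 1, edges = rbind(c(1, 2), c(2, 3)))
  chain$reaches$area <- c(1, 2, 3)
  expect_equal(unname(accumulate_upstream(chain, "area")), c(1, 3, 6))

  # parent 1 (acc 10) diverges into main 2 and secondary 3
  div <- tiny_net(1:3, 1, flag = c("none", "main", "secondary"),
                  edges = rbind(c(1, 2), c(1, 3)))
  div$reaches$area <- c(10, 1, 2)
  acc <- accumulate_upstream(div, "area")
  expect_equal(unname(acc[["2"]]), 11)   # 10 + local
  expect_equal(unname(acc[["3"]]), 2)    # local only
  expect_error(accumulate_upstream(chain, "nope"), "schema error")
})

test_that("stored generator orders and accumulated counts match brute force on dendritic networks", {
  for (seed in 1:4) {
    cfg <- generator_config(n_reaches = 80, divergence_rate = 0,
                            split_rate = 0, seed = seed)
    net <- generate_dendritic_network(cfg)
    expect_identical(
      unname(compute_strahler_order(net)),
      unname(brute_strahler(net$edges, net$reaches$comid)))
    expect_identical(net$reaches$strahler_order,
                     unname(brute_strahler(net$edges, net$reaches$comid)))
    net$reaches$one <- 1
    acc <- accumulate_upstream(net, "one")
    sub <- sample(net$reaches$comid, 10)
    for (cid in sub)
      expect_equal(unname(acc[[as.character(cid)]]),
                   brute_upstream_count(net$edges, cid) + 1)
  }
})
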