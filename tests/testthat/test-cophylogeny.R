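test_that("expand_host_tree grafts, relabels and prunes correctly", {
  host <- parse_newick("(H1,(H2,H3));")
  m <- data.frame(virus_tip = c("v1", "v2", "v3"),
                  host_tip = c("H1", "H2", "H3"))
  ex <- expand_host_tree(host, m)
  expect_setequal(ex$tip.label, c("v1", "v2", "v3"))
  expect_true(ape::is.monophyletic(ex, c("v2", "v3")))

  # two viruses on H1, H3 unmapped and pruned
  m2 <- data.frame(virus_tip = c("v1", "v2", "v3"),
                   host_tip = c("H1", "H1", "H2"))
  ex2 <- expand_host_tree(host, m2)
  expect_setequal(ex2$tip.label, c("v1", "v2", "v3"))
  expect_true(ape::is.monophyletic(ex2, c("v1", "v2")))

  # all viruses on one host: star
  m3 <- data.frame(virus_tip = paste0("v", 1:4), host_tip = "H2")
  ex3 <- expand_host_tree(host, m3)
  expect_equal(ex3$Nnode, 1L)

  expect_error(expand_host_tree(host, data.frame(virus_tip = "v1",
                                                 host_tip = "H9")),
               "absent from the cladogram")
})

test_that("nPH85 is 0 on identical topologies and 1 on disjoint split sets", {
  host <- sim_host_tree(6, seed = 2)
  m <- data.frame(virus_tip = paste0("v", 1:6), host_tip = paste0("H", 1:6))
  vt <- host
  vt$tip.label <- paste0("v", 1:6)
  expect_equal(nph85(vt, host, m)$distance, 0)

  host4 <- parse_newick("((H1,H2),(H3,H4));")
  m4 <- data.frame(virus_tip = c("a", "b", "c", "d"),
                   host_tip = c("H1", "H2", "H3", "H4"))
  conflict <- parse_newick("((a,c),(b,d));")
  expect_equal(nph85(conflict, host4, m4)$distance, 1)
  expect_error(nph85(parse_newick("((a,b),c);"), host4, m4[1:3, ]),
               "at least 4")
})

test_that("nPH85 equals the normalized symmetric split difference (oracle)", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- random_bltree(n)
    b <- random_bltree(n)
    ka <- brute_force_splits(a); kb <- brute_force_splits(b)
    expected <- (length(setdiff(ka, kb)) + length(setdiff(kb, ka))) /
      (length(ka) + length(kb))
    host <- b
    host$tip.label <- sub("^t", "H", host$tip.label)
    m <- data.frame(virus_tip = a$tip.label,
                    host_tip = sub("^t", "H", a$tip.label))
    got <- nph85(a, host, m)$distance
    expect_equal(got, expected, tolerance = 1e-12)
    # symmetry and range
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("resample-one-per-host mode is seeded and bounded", {
  host <- sim_host_tree(5, seed = 4)
  m <- data.frame(virus_tip = paste0("v", 1:10),
                  host_tip = paste0("H", rep(1:5, each = 2)))
  vt <- ape::rtree(10)
  vt$tip.label <- paste0("v", 1:10)
  r1 <- nph85(vt, host, m, mode = "resample-one-per-host", resamples = 20, seed = 9)
  r2 <- nph85(vt, host, m, mode = "resample-one-per-host", resamples = 20, seed = 9)
  expect_identical(r1$per_draw, r2$per_draw)
  expect_true(all(r1$per_draw >= 0 & r1$per_draw <= 1))
})

test_that("reconciliation DP equals exhaustive enumeration on random instances", {
  set.seed(24)
  for (i in 1:60) {
    inst <- random_dtl_instance(sample(3:5, 1), sample(3:5, 1))
    bf <- brute_force_dtl(inst$virus, inst$host, inst$map)
    dp <- reconcile_mpr(inst$virus, inst$host, inst$map)
    expect_equal(dp$min_cost, bf$min_cost)
    expect_equal(dp$mpr_count, bf$mpr_count)
  }
  # non-default costs
  for (i in 1:20) {
    inst <- random_dtl_instance(4, 4)
    cc <- c(cospeciation = 0, transfer = 2, duplication = 1, loss = 1)
    bf <- brute_force_dtl(inst$virus, inst$host, inst$map, cc)
    dp <- reconcile_mpr(inst$virus, inst$host, inst$map,
                        event_costs(0, 2, 1, 1))
    expect_equal(dp$min_cost, bf$min_cost)
    expect_equal(dp$mpr_count, bf$mpr_count)
  }
})

test_that("worked reconciliation examples behave as expected", {
  # perfect congruence: cost 0, n-1 cospeciations, single MPR
  host <- sim_host_tree(7, seed = 5)
  m <- data.frame(virus_tip = paste0("v", 1:7), host_tip = paste0("H", 1:7))
  vt <- host; vt$tip.label <- paste0("v", 1:7)
  rec <- reconcile_mpr(vt, host, m)
  expect_equal(rec$min_cost, 0)
  expect_equal(rec$mpr_count, 1)
  el <- event_likelihoods(rec, n_samples = 5, seed = 1)
  expect_true(all(el$per_sample[, "cospeciation"] == 6))
  expect_true(all(el$per_sample[, c("transfer", "duplication", "loss")] == 0))
  expect_equal(unname(el$event_proportions[["cospeciation"]]), 1)

  # one cross-species transmission
  ht <- parse_newick("((A,B),C);")
  vt2 <- parse_newick("((a,c),b);")
  m2 <- data.frame(virus_tip = c("a", "b", "c"), host_tip = c("A", "B", "C"))
  expect_equal(reconcile_mpr(vt2, ht, m2)$min_cost, 1)

  # duplication cherry
  vt3 <- parse_newick("((a,b),c);")
  m3 <- data.frame(virus_tip = c("a", "b", "c"), host_tip = c("A", "A", "B"))
  rec3 <- reconcile_mpr(vt3, ht, m3)
  expect_equal(rec3$min_cost, 1)
  el3 <- event_likelihoods(rec3, n_samples = 5, seed = 1)
  expect_true(all(el3$per_sample[, "duplication"] == 1))

  # polytomies: error for virus, seeded resolution for host
  expect_error(reconcile_mpr(parse_newick("((a,b,c),d);"), ht,
                             rbind(m2, data.frame(virus_tip = "d", host_tip = "C"))),
               "polytomies")
  hpoly <- parse_newick("(A,B,C,D);")
  m4 <- data.frame(virus_tip = c("a", "b", "c", "d"),
                   host_tip = c("A", "B", "C", "D"))
  r4a <- reconcile_mpr(parse_newick("((a,b),(c,d));"), hpoly, m4, seed = 3)
  r4b <- reconcile_mpr(parse_newick("((a,b),(c,d));"), hpoly, m4, seed = 3)
  expect_true(r4a$host_resolved)
  expect_identical(write_newick(r4a$host_tree), write_newick(r4b$host_tree))
  expect_error(reconcile_mpr(vt2, ht, m2[1:2, ]), "unmapped")
})

test_that("MPR sampling is uniform and proportions sum to one", {
  # frozen instance with exactly 2 MPRs of distinct event signature:
  # one transfer-bearing, one duplication+loss-bearing, equal cost under
  # costs (0, 2, 1, 1)
  vt <- parse_newick("((v1,v2),v3);")
  ht <- parse_newick("(H1,((H2,H3),H4));")
  m <- data.frame(virus_tip = c("v1", "v2", "v3"),
                  host_tip = c("H2", "H3", "H3"))
  cc <- event_costs(cospeciation = 0, transfer = 2, duplication = 1, loss = 1)
  bf <- brute_force_dtl(vt, ht, m, c(cospeciation = 0, transfer = 2,
                                     duplication = 1, loss = 1))
  expect_equal(bf$mpr_count, 2)
  rec <- reconcile_mpr(vt, ht, m, cc)
  expect_equal(rec$mpr_count, 2)
  el <- event_likelihoods(rec, n_samples = 2000, seed = 6)
  sig <- apply(el$per_sample, 1, paste, collapse = "-")
  tab <- table(sig)
  expect_length(tab, 2L)
  # 3-sigma binomial band around 0.5 at n = 2000
  p_hat <- tab[[1]] / 2000
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2000))
  # proportions sum to 1 on random instances
  set.seed(26)
  for (i in 1:10) {
    inst <- random_dtl_instance(sample(4:6, 1), sample(4:6, 1))
    r <- reconcile_mpr(inst$virus, inst$host, inst$map)
    e <- event_likelihoods(r, n_samples = 30, seed = i)
    shares <- rowSums(e$per_sample / rowSums(e$per_sample))
    expect_true(all(abs(shares - 1) < 1e-9))
    expect_equal(sum(e$event_proportions[c("cospeciation", "transfer",
                                           "duplication", "loss")]), 1,
                 tolerance = 1e-9)
    # every sampled reconciliation attains the minimum cost
    costs <- r$costs
    sample_costs <- e$per_sample %*% c(costs[["cospeciation"]], costs[["transfer"]],
                                       costs[["duplication"]], costs[["loss"]])
    expect_true(all(abs(sample_costs - r$min_cost) < 1e-9))
  }
})

test_that("sampling is reproducible bit-for-bit given the seed", {
  inst <- random_dtl_instance_seeded(6, 5, seed = 99)
  rec <- reconcile_mpr(inst$virus, inst$host, inst$map)
  a <- event_likelihoods(rec, n_samples = 50, seed = 12)
  b <- event_likelihoods(rec, n_samples = 50, seed = 12)
  expect_identical(a$per_sample, b$per_sample)
})
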