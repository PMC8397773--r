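mk_net <- function(v, n, ids = sprintf("m%02d", 1:n)) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- v
  structure(m + t(m), kind = "SRI", window_minutes = 720,
            class = c("assoc_matrix", "matrix"))
}

test_that("edge thinning keeps the strongest edges with seeded tie-breaks", {
  set.seed(9)
  w <- sort(runif(10), decreasing = TRUE)
  net <- mk_net(w, 5)
  thin <- thin_network(net, 4, seed = 1)
  kept <- sort(thin[upper.tri(thin)][thin[upper.tri(thin)] > 0],
               decreasing = TRUE)
  expect_equal(kept, w[1:4])  # exactly the 4 largest, weights untouched

  # identity when the target equals the current edge count
  same <- thin_network(net, 10, seed = 1)
  expect_equal(as.vector(unclass(same)), as.vector(unclass(net)))
  expect_true(attr(same, "thinned"))

  expect_error(thin_network(net, 11), "exceeds")

  # ties at the cutoff: .5 always kept, exactly one of the two .4s,
  # reproducibly under the same seed
  tied <- mk_net(c(0.5, 0.4, 0.4, 0.3, 0.1,
                   rep(0, 10)), 6)
  t1 <- thin_network(tied, 2, seed = 7)
  t2 <- thin_network(tied, 2, seed = 7)
  expect_identical(unclass(t1), unclass(t2))
  kept1 <- t1[upper.tri(t1)][t1[upper.tri(t1)] > 0]
  expect_equal(sort(kept1, decreasing = TRUE), c(0.5, 0.4))
  # a different seed may keep the other tied edge but never a weight change
  t3 <- thin_network(tied, 2, seed = 8)
  expect_equal(sort(t3[upper.tri(t3)][t3[upper.tri(t3)] > 0],
                    decreasing = TRUE), c(0.5, 0.4))
})

test_that("the thinning null pairs real and density-matched estimates", {
  st <- small_sim(seed = 17, n_nights = 30)
  evs <- detect_associations(st$records, st$individuals, c(2, 720))
  sri2 <- adjusted_sri(evs[["2"]])
  sri12 <- adjusted_sri(evs[["720"]])
  ctf <- suppressMessages(filter_community(st$community))
  sim <- jaccard_similarity(ctf)
  sp <- spatial_summary(st$records)
  bd <- function(m) suppressMessages(
    build_dyad_table(sim, m, sp, st$kinship, st$individuals, st$samples))
  res <- thinning_null_analysis(sri12, list(`2` = sri2, `720` = sri12), bd,
                                n_perm = 99, seed = 1)
  expect_equal(nrow(res), 2)
  # thinned network edge count equals each real network's edge count
  expect_equal(res$n_edges_thinned, res$n_edges_real)
  # thinning the reference to its own edge count is the identity
  row12 <- res[res$window == "720", ]
  expect_equal(row12$estimate_thinned, row12$estimate_real)
  expect_equal(row12$p_thinned, row12$p_real)
})

test_that("family dropout covers every family and preserves dyad counts", {
  st <- small_sim(seed = 19, n_nights = 30)
  evs <- detect_associations(st$records, st$individuals, c(2, 720))
  nets <- list(`12h` = adjusted_sri(evs[["720"]]),
               `2min` = adjusted_sri(evs[["2"]]))
  ctf <- suppressMessages(filter_community(st$community))
  sp <- spatial_summary(st$records)
  res <- suppressMessages(family_dropout(
    ctf, nets, sp, st$kinship, st$individuals, st$samples,
    n_perm = 99, seed = 1))
  fams <- unique(ctf$taxonomy$Family)
  expect_equal(nrow(res), length(fams) * 2)  # one row per family x network
  expect_setequal(unique(res$family), fams)
  expect_true(all(is.finite(res$estimate)))
  # excluding a family never changes the dyad count (no sample emptied here)
  expect_equal(length(unique(res$n_dyads)), 1)
  # log richness recorded for each family
  expect_equal(sort(res$n_asvs_family[res$network == "12h"]),
               sort(unname(as.vector(table(ctf$taxonomy$Family)))))

  # partition property: any family plus the rest reconstitutes the table
  f <- fams[1]
  in_f <- ctf$taxonomy$Family == f
  expect_equal(sum(in_f) + sum(!in_f), ncol(ctf$counts))
})

test_that("dropping an all-zero family is a no-op on the social estimate", {
  st <- small_sim(seed = 23, n_nights = 20)
  ev <- detect_associations(st$records, st$individuals, 720)
  net <- list(`12h` = adjusted_sri(ev))
  sp <- spatial_summary(st$records)
  # append a ghost family with zero counts everywhere (unfiltered table)
  counts <- cbind(st$community$counts,
                  ghost1 = 0, ghost2 = 0)
  tax <- dplyr::bind_rows(
    st$community$taxonomy,
    tibble::tibble(asv_id = c("ghost1", "ghost2"), Kingdom = "Bacteria",
                   Phylum = "P1", Class = "C1", Order = "O1",
                   Family = "FamGhost"))
  ct <- community_table(counts, tax)
  res <- suppressMessages(family_dropout(
    ct, net, sp, st$kinship, st$individuals, st$samples,
    n_perm = 99, seed = 1))
  full_sim <- jaccard_similarity(ct)
  dy <- suppressMessages(build_dyad_table(
    full_sim, net[[1]], sp, st$kinship, st$individuals, st$samples))
  full_fit <- fit_dyadic_model(dy, n_perm = 99, seed = 1)
  full_soc <- dplyr::filter(tidy(full_fit), term == "social_strength")
  ghost <- res[res$family == "FamGhost", ]
  expect_equal(ghost$estimate, full_soc$estimate)
  expect_equal(ghost$p_perm, full_soc$p_perm)
})

test_that("a family whose removal empties samples is flagged and samples dropped", {
  # one sample supported only by FamB empties when FamB is dropped
  counts <- rbind(s1 = c(5, 3, 0, 0, 2, 0), s2 = c(0, 0, 0, 7, 0, 0),
                  s3 = c(2, 2, 2, 2, 0, 3), s4 = c(4, 0, 1, 0, 5, 1),
                  s5 = c(1, 6, 0, 2, 2, 2))
  ct <- make_community(counts, families = c("FamA", "FamA", "FamA", "FamB",
                                            "FamC", "FamC"))
  ids <- c("A", "B", "C", "D", "E")
  ind <- make_individuals(ids)
  samples <- tibble::tibble(sample_id = rownames(counts),
                            individual_id = ids,
                            collection_date = base_night + 0:4)
  set.seed(2)
  xy <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  sp <- as.matrix(dist(xy)); dimnames(sp) <- list(ids, ids)
  kin <- diag(5); dimnames(kin) <- list(ids, ids)
  net <- mk_net(runif(10) * rbinom(10, 1, 0.6), 5, ids)
  expect_message(
    res <- family_dropout(ct, list(`12h` = net), sp, kin, ind, samples,
                          n_perm = 99, seed = 1),
    "empties")
  expect_equal(res$flag[res$family == "FamB"], "empties_samples")
})
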