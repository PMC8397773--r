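# a hand-buildable analysis set: n individuals with explicit pairwise
# structures, one or more samples each, response assembled on the logit scale
make_dyad_setup <- function(n_ind = 20, samples_per = 1, seed = 1,
                            beta_social = 0, noise_sd = 0.5) {
  withr::with_seed(seed, {
    ids <- sprintf("i%02d", seq_len(n_ind))
    soc <- matrix(0, n_ind, n_ind, dimnames = list(ids, ids))
    soc[upper.tri(soc)] <- runif(choose(n_ind, 2)) *
      rbinom(choose(n_ind, 2), 1, 0.5)
    soc <- soc + t(soc)
    coords <- cbind(runif(n_ind, 0, 100), runif(n_ind, 0, 100))
    dmat <- as.matrix(dist(coords))
    dimnames(dmat) <- list(ids, ids)
    kin <- matrix(0, n_ind, n_ind, dimnames = list(ids, ids))
    kin[upper.tri(kin)] <- sample(c(0, 0.25, 0.5), choose(n_ind, 2), TRUE,
                                  prob = c(0.8, 0.1, 0.1))
    kin <- kin + t(kin); diag(kin) <- 1
    individuals <- make_individuals(ids)
    samples <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n_ind * samples_per)),
      individual_id = rep(ids, each = samples_per),
      collection_date = base_night + sample(0:60, n_ind * samples_per, TRUE))
    # similarity with a known social coefficient on the logit scale
    ns <- nrow(samples)
    sim <- matrix(0, ns, ns,
                  dimnames = list(samples$sample_id, samples$sample_id))
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      if (a >= b) next
      eta <- -1 + beta_social * soc[samples$individual_id[a],
                                    samples$individual_id[b]] +
        rnorm(1, 0, noise_sd)
      sim[a, b] <- sim[b, a] <- plogis(eta)
    }
    diag(sim) <- 1
    sim <- structure(sim, metric = "jaccard_index")
    list(ids = ids, soc = structure(soc, kind = "SRI", window_minutes = 720,
                                    class = c("assoc_matrix", "matrix")),
         dmat = dmat, kin = kin, individuals = individuals,
         samples = samples, sim = sim)
  })
}

test_that("the dyad table enumerates between-individual sample pairs with scaled covariates", {
  su <- make_dyad_setup(n_ind = 3, samples_per = 2, seed = 2)
  dy <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, su$individuals,
                         su$samples)
  expect_equal(nrow(dy), 12)  # C(6,2) = 15 minus 3 within-individual
  expect_true(all(dy$id_a != dy$id_b))
  expect_true(all(!duplicated(paste(pmin(dy$sample_a, dy$sample_b),
                                    pmax(dy$sample_a, dy$sample_b)))))
  for (cl in c("similarity", "social_strength", "spatial_distance",
               "sampling_interval", "kinship", "sex_same", "age_same")) {
    expect_true(all(dy[[cl]] >= 0 & dy[[cl]] <= 1), info = cl)
  }
  expect_equal(max(dy$spatial_distance), 1)  # min-max scaling
  expect_equal(min(dy$spatial_distance), 0)
  # sex categories follow the two sexes (helper alternates F/M)
  mm <- dy[dy$id_a == "i02" & dy$id_b == "i02", ]
  expect_true(all(dy$dyad_sex_category[dy$sex_same == 1 &
                                         dy$id_a == "i01"] == "FF"))
  expect_setequal(unique(dy$dyad_sex_category), c("FF", "MF"))
})

test_that("the dyadic model recovers a known social coefficient", {
  su <- make_dyad_setup(n_ind = 30, seed = 4, beta_social = 1,
                        noise_sd = 0.5)
  dy <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, su$individuals,
                         su$samples)
  fit <- fit_dyadic_model(dy, n_perm = 199, seed = 1)
  soc <- dplyr::filter(tidy(fit), term == "social_strength")
  expect_lt(abs(soc$estimate - 1), 0.3)
  expect_lte(soc$p_perm, 0.05)
  expect_true(soc$conf_low <= soc$estimate & soc$estimate <= soc$conf_high)
  # p-values live on the achievable permutation grid
  expect_true(all(tidy(fit)$p_perm >= 1 / 200 & tidy(fit)$p_perm <= 1))
  # determinism of the permutation machinery
  fit2 <- fit_dyadic_model(dy, n_perm = 199, seed = 1)
  expect_identical(tidy(fit), tidy(fit2))
  expect_equal(glance(fit)$n_perm, 199)
  expect_equal(glance(fit)$seed, 1)
})

test_that("degenerate designs are handled as specified", {
  su <- make_dyad_setup(n_ind = 10, seed = 6)
  dy <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, su$individuals,
                         su$samples)
  # constant covariates: estimate 0, p 1, flagged
  dy0 <- dy
  dy0$social_strength <- 0
  dy0$kinship <- 0
  fit <- fit_dyadic_model(dy0, n_perm = 99, seed = 1)
  soc <- dplyr::filter(tidy(fit), term == "social_strength")
  expect_equal(soc$estimate, 0)
  expect_equal(soc$p_perm, 1)
  expect_equal(soc$flag, "constant")

  # constant response
  dyc <- dy; dyc$similarity <- 0.4
  expect_error(fit_dyadic_model(dyc, n_perm = 99), "Constant response")

  # collinear pair named
  dyl <- dy; dyl$kinship <- 2 * dyl$social_strength
  expect_error(fit_dyadic_model(dyl, n_perm = 99), "social_strength.*kinship")

  expect_error(fit_dyadic_model(dy, n_perm = 50), "at least 99")
})

test_that("sex-interaction slopes are per category and availability-aware", {
  su <- make_dyad_setup(n_ind = 16, seed = 8, beta_social = 1)
  dy <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, su$individuals,
                         su$samples)
  fit <- fit_sex_interaction(dy, n_perm = 99, seed = 2)
  td <- tidy(fit)
  expect_setequal(intersect(c("social_FF", "social_MF", "social_MM"),
                            td$term),
                  c("social_FF", "social_MF", "social_MM"))
  expect_equal(fit$variant, "sex_interaction")

  # all-male population: only the MM slope is estimable
  ind_m <- su$individuals
  ind_m$sex <- "M"
  dym <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, ind_m, su$samples)
  fitm <- fit_sex_interaction(dym, n_perm = 99, seed = 2)
  tdm <- tidy(fitm)
  expect_true("social_MM" %in% tdm$term)
  expect_false(any(c("social_FF", "social_MF") %in% tdm$term))
})

test_that("MRQAP matches normal-equation OLS and flags the generating predictor", {
  # 4-node worked example, hand-computable coefficients
  ids <- letters[1:4]
  mk <- function(v) {
    m <- matrix(0, 4, 4, dimnames = list(ids, ids))
    m[upper.tri(m)] <- v
    m + t(m)
  }
  x1 <- mk(c(1, 2, 3, 4, 5, 6))
  x2 <- mk(c(2, 1, 0, 1, 3, 2))
  y <- mk(c(1, 2, 3, 4, 5, 6) * 2 + c(2, 1, 0, 1, 3, 2) * -1 + 3)
  fit <- mrqap(y, list(first = x1, second = x2), n_perm = 99, seed = 1)
  X <- cbind(1, c(1, 2, 3, 4, 5, 6), c(2, 1, 0, 1, 3, 2))
  expect_equal(tidy(fit)$estimate, oracle_ols(X, y[upper.tri(y)]),
               tolerance = 1e-8)

  # response an exact function of one predictor: smallest achievable p
  set.seed(2)
  n <- 12
  z1 <- mk6 <- matrix(0, n, n); z1[upper.tri(z1)] <- runif(choose(n, 2))
  z1 <- z1 + t(z1)
  z2 <- matrix(0, n, n); z2[upper.tri(z2)] <- runif(choose(n, 2))
  z2 <- z2 + t(z2)
  resp <- 2 * z1
  fit2 <- mrqap(resp, list(gen = z1, noise = z2), n_perm = 99, seed = 3)
  td <- tidy(fit2)
  expect_equal(td$p_perm[td$term == "gen"], 1 / 100)

  expect_error(mrqap(resp[1:3, 1:4], list(a = z1)), "square")
  asym <- z1; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mrqap(resp, list(a = asym)), "symmetric")
})

test_that("Mantel kinship test and individual aggregation behave", {
  su <- make_dyad_setup(n_ind = 12, samples_per = 2, seed = 10)
  isim <- individual_similarity(su$sim, su$samples)
  expect_equal(dim(isim), c(12, 12))
  # aggregation is the mean over between-individual sample pairs
  blk <- su$sim[su$samples$sample_id[su$samples$individual_id == "i01"],
                su$samples$sample_id[su$samples$individual_id == "i02"]]
  expect_equal(isim["i01", "i02"], mean(blk))

  # a matrix against itself correlates perfectly
  mk <- mantel_kinship(isim, isim, n_perm = 99, seed = 1)
  expect_equal(mk$r, 1)
  mk2 <- mantel_kinship(isim, su$kin, n_perm = 99, seed = 1)
  expect_true(mk2$p >= 1 / 100 && mk2$p <= 1)
})

test_that("PERMANOVA attributes all variation to a perfectly separating factor", {
  ids <- paste0("s", 1:6)
  sim <- matrix(0, 6, 6, dimnames = list(ids, ids))
  sim[1:3, 1:3] <- 1
  sim[4:6, 4:6] <- 1
  diag(sim) <- 1
  sim <- structure(sim, metric = "jaccard_index")
  fac <- data.frame(sample_id = ids, group = rep(c("g1", "g2"), each = 3))
  res <- permanova(sim, fac, n_perm = 199, seed = 1)
  expect_equal(res$R2[res$term == "group"], 1)

  expect_error(permanova(sim, data.frame(sample_id = ids, g = "x"),
                         n_perm = 99), "single level")
})

test_that("the sampling-interval covariate keeps its own values under permutation", {
  # two samples per individual so intervals vary within dyads; a fit must
  # use each row's interval, not a per-dyad constant
  su <- make_dyad_setup(n_ind = 8, samples_per = 2, seed = 12)
  dy <- build_dyad_table(su$sim, su$soc, su$dmat, su$kin, su$individuals,
                         su$samples)
  y <- qlogis(pmin(pmax(dy$similarity, 1e-6), 1 - 1e-6))
  # age_same is constant under the helper's all-adult metadata
  X <- cbind(1, dy$social_strength, dy$spatial_distance, dy$kinship,
             dy$sex_same, dy$sampling_interval)
  ref <- oracle_ols(X, y)
  fit <- fit_dyadic_model(dy, n_perm = 99, seed = 1)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "social_strength"], ref[2],
               tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "sampling_interval"], ref[6],
               tolerance = 1e-8)
})
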