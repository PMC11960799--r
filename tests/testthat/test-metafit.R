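test_that("single-component REML reduces to the known closed form", {
  # one record per study, equal sampling variances: between-study REML
  # variance equals max(0, sample variance - v)
  set.seed(70)
  y <- rnorm(20, 0, 1.5)
  v <- 0.4
  d <- data.frame(yi = y, vi = v)
  f <- meta_fit(yi ~ 1, vi = vi, data = d, random = "es")
  expect_equal(unname(f$sigma2["es"]), max(0, var(y) - v),
               tolerance = 1e-6)
  expect_equal(unname(coef(f)), mean(y), tolerance = 1e-8)
})

test_that("identical effects with equal variances give that value and zero components", {
  d <- data.frame(yi = rep(-0.7, 12), vi = 0.2,
                  study = rep(1:4, each = 3), species = rep(1:3, 4))
  f <- meta_fit(yi ~ 1, vi = vi, data = d, study = study,
                species = species)
  expect_equal(unname(coef(f)), -0.7, tolerance = 1e-8)
  expect_true(all(f$sigma2 < 1e-6))
})

test_that("the fit matches an independent multilevel REML implementation", {
  skip_if_not_installed("metafor")
  sim <- sim_meta_data(meta_sim_config(n_studies = 15, es_per_study = 4,
                                       n_species = 12, seed = 19))
  d <- sim$records; d$es_id <- seq_len(nrow(d)); d$sp2 <- d$species
  f <- meta_fit(yi ~ 1, vi = vi, data = d, study = study,
                species = species, A = sim$A)
  m <- metafor::rma.mv(yi, vi,
                       random = list(~1 | study, ~1 | es_id,
                                     ~1 | species, ~1 | sp2),
                       R = list(sp2 = sim$A), Rscale = "none",
                       data = d, method = "REML")
  expect_equal(unname(coef(f)), unname(coef(m)), tolerance = 1e-5)
  expect_equal(unname(f$se), unname(m$se), tolerance = 1e-4)
  expect_equal(unname(f$sigma2), unname(m$sigma2), tolerance = 1e-4)
  expect_equal(f$logLik, as.numeric(stats::logLik(m)), tolerance = 1e-5)

  # moderator model coefficients too
  fm <- moderator_test(d, "event_type", A = sim$A)
  mm <- metafor::rma.mv(yi, vi, mods = ~ 0 + event_type,
                        random = list(~1 | study, ~1 | es_id,
                                      ~1 | species, ~1 | sp2),
                        R = list(sp2 = sim$A), Rscale = "none",
                        data = d, method = "REML")
  expect_equal(unname(coef(fm)), unname(coef(mm)), tolerance = 1e-4)
})

test_that("the REML solution is a local optimum of the restricted likelihood", {
  sim <- sim_meta_data(meta_sim_config(n_studies = 12, es_per_study = 3,
                                       n_species = 8, seed = 23))
  f <- meta_fit(yi ~ 1, vi = vi, data = sim$records, study = study,
                species = species, A = sim$A)
  ll0 <- reml_logLik(f)
  expect_equal(ll0, f$logLik, tolerance = 1e-8)
  set.seed(1)
  for (r in 1:12) {
    pert <- f$sigma2 * exp(rnorm(4, sd = 0.2)) + runif(4, 0, 0.02)
    expect_lte(reml_logLik(f, pert), ll0 + 1e-7)
  }
})

test_that("with the phylogenetic component fixed at zero the fit ignores A", {
  sim <- sim_meta_data(meta_sim_config(n_studies = 10, es_per_study = 3,
                                       n_species = 8, seed = 29))
  d <- sim$records
  A2 <- diag(nrow(sim$A)); dimnames(A2) <- dimnames(sim$A)
  f1 <- meta_fit(yi ~ 1, vi = vi, data = d, study = study,
                 species = species, A = sim$A,
                 sigma2_fixed = c(phylo = 0))
  f2 <- meta_fit(yi ~ 1, vi = vi, data = d, study = study,
                 species = species, A = A2,
                 sigma2_fixed = c(phylo = 0))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-6)
})

test_that("I2 shares sum to the total and follow the algebraic identities", {
  sim <- sim_meta_data(meta_sim_config(n_studies = 12, es_per_study = 4,
                                       n_species = 10, seed = 31))
  f <- meta_fit(yi ~ 1, vi = vi, data = sim$records, study = study,
                species = species, A = sim$A)
  expect_lt(abs(sum(f$I2$by_level) - f$I2$total), 1e-10)
  # all components zero -> I2 = 0
  d0 <- data.frame(yi = rep(1, 10), vi = 0.3)
  f0 <- meta_fit(yi ~ 1, vi = vi, data = d0, random = "es")
  expect_equal(heterogeneity(f0)$total, 0, tolerance = 1e-4)
  # one component equal to the typical sampling variance -> I2 = 50%
  h <- f$I2
  fmock <- f
  fmock$sigma2 <- c(study = h$vbar, es = 0, species = 0, phylo = 0)
  expect_equal(heterogeneity(fmock)$total, 50)
})

test_that("the pooled estimate lies within the range of the effects", {
  for (seed in c(37, 41)) {
    sim <- sim_meta_data(meta_sim_config(n_studies = 10, es_per_study = 3,
                                         n_species = 8, seed = seed))
    f <- meta_fit(yi ~ 1, vi = vi, data = sim$records, study = study,
                  species = species, A = sim$A)
    expect_gte(unname(coef(f)), min(sim$records$yi))
    expect_lte(unname(coef(f)), max(sim$records$yi))
  }
})

test_that("moderator machinery: planted offsets, Q_M and marginal R2", {
  # two event types with a planted 1.0 offset and tiny noise
  set.seed(43)
  k <- 60
  ev <- rep(c("warming", "ros"), each = k / 2)
  d <- data.frame(yi = ifelse(ev == "warming", -0.5, 0.5) +
                    rnorm(k, 0, 0.05),
                  vi = 0.01, study = rep(1:12, each = 5),
                  species = rep(1:6, 10), event_type = ev)
  f <- moderator_test(d, "event_type")
  est <- sort(unname(coef(f)))
  expect_equal(est, c(-0.5, 0.5), tolerance = 0.1)
  expect_lt(f$QM_p, 1e-6)
  expect_equal(f$QM_df, 1L)
  expect_gt(f$R2_marginal, 50)

  # constant moderator: no explainable variance, Q_M undefined
  d$const <- "one-level"
  fc <- moderator_test(d, "const")
  expect_equal(fc$R2_marginal, 0)
  expect_true(is.na(fc$QM))

  # intercept model Q_M tests the non-intercept coefficients
  fi <- meta_fit(yi ~ event_type, vi = vi, data = d, study = study,
                 species = species)
  expect_equal(fi$QM_df, 1L)
  expect_lt(fi$QM_p, 1e-6)
})

test_that("Q_M null distribution is chi-square under label permutation", {
  set.seed(47)
  k <- 80
  d0 <- data.frame(yi = rnorm(k, 0, 0.5), vi = runif(k, 0.05, 0.2),
                   study = rep(1:20, each = 4))
  qms <- replicate(40, {
    d0$m <- sample(rep(c("a", "b", "c"), length.out = k))
    f <- moderator_test(d0, "m", control = meta_control(starts = 1))
    f$QM
  })
  # compare against chi-square df = 2 moments loosely
  expect_equal(mean(qms), 2, tolerance = 0.6)
  expect_gt(ks.test(qms, "pchisq", df = 2)$p.value, 0.01)
})

test_that("prediction intervals contain confidence intervals", {
  sim <- sim_meta_data(meta_sim_config(n_studies = 12, es_per_study = 3,
                                       n_species = 8, seed = 53))
  f <- meta_fit(yi ~ 1, vi = vi, data = sim$records, study = study,
                species = species, A = sim$A)
  expect_lt(f$pi.lb[1], f$ci.lb[1])
  expect_gt(f$pi.ub[1], f$ci.ub[1])
  pr <- predict(f)
  expect_equal(pr$pred, unname(coef(f)))
  expect_equal(pr$ci.lb, unname(f$ci.lb))
  pr2 <- predict(f, newdata = data.frame(x = 1))
  expect_equal(pr2$pred, unname(coef(f)))
})

test_that("authorship-group check recovers planted differences", {
  set.seed(59)
  k <- 60
  grp <- rep(c("lead", "other"), each = k / 2)
  d <- data.frame(yi = ifelse(grp == "lead", -0.8, -0.8) +
                    rnorm(k, 0, 0.3),
                  vi = runif(k, 0.02, 0.1), study = rep(1:12, each = 5),
                  species = rep(1:5, 12), author_group = grp)
  pb <- publication_bias_check(d)
  expect_equal(nrow(pb$groups), 2)
  expect_gt(pb$diff_p, 0.01)          # no planted difference
  d2 <- d; d2$yi <- d2$yi + ifelse(grp == "other", 1.5, 0)
  pb2 <- publication_bias_check(d2)
  expect_lt(pb2$diff_p, 0.001)
  diffs <- diff(pb2$groups$estimate)
  expect_equal(abs(diffs), 1.5, tolerance = 0.25)
  d3 <- d[d$author_group == "lead", ]
  expect_error(publication_bias_check(d3), "non-empty")
})

test_that("species absent from the correlation matrix abort the fit", {
  sim <- sim_meta_data(meta_sim_config(n_studies = 6, es_per_study = 2,
                                       n_species = 5, seed = 61))
  A <- sim$A[1:3, 1:3]
  expect_error(meta_fit(yi ~ 1, vi = vi, data = sim$records,
                        study = study, species = species, A = A),
               "absent from the correlation matrix")
})
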