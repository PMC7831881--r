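test_that("standardization yields exact z-scores", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  x <- rnorm(30)
  expect_equal(standardize(3 * x + 7), standardize(x), tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), class = "pauseflow_validation_error")
})

sim_lmm_data <- function(n_animals = 8, n_obs = 200, beta_t = 0.5,
                         sd_animal = 1, sd_e = 0.5, beta_co2 = 0,
                         beta_int = 0) {
  temps <- c(12, 14, 16, 18, 20)
  g <- expand.grid(animal_id = paste0("a", seq_len(n_animals)),
                   temperature = temps,
                   co2_level = c("normocapnia", "hypercapnia"))
  g <- g[rep(seq_len(nrow(g)), each = n_obs), ]
  intercepts <- rnorm(n_animals, 0, sd_animal)
  names(intercepts) <- paste0("a", seq_len(n_animals))
  tstep <- (g$temperature - 12) / 2
  hyp <- as.numeric(g$co2_level == "hypercapnia")
  g$value <- intercepts[g$animal_id] + beta_t * tstep + beta_co2 * hyp +
    beta_int * tstep * hyp + rnorm(nrow(g), 0, sd_e)
  g
}

test_that("mixed model recovers noiseless effects exactly", {
  d <- expand.grid(animal_id = c("a1", "a2"),
                   temperature = c(12, 20),
                   co2_level = c("normocapnia", "hypercapnia"))
  d <- d[rep(1:8, each = 3), ]
  d$value <- 2 + 0.5 * (d$temperature == 20) +
    1 * (d$co2_level == "hypercapnia")
  fit <- suppressWarnings(fit_activity_lmm(d)) # zero-noise degenerate fit
  est <- fit$fixed$estimate
  names(est) <- fit$fixed$term
  expect_equal(unname(est["temperature20"]), 0.5, tolerance = 1e-8)
})

test_that("zero animal variance reduces the mixed model to OLS", {
  set.seed(200)
  d <- sim_lmm_data(n_animals = 6, n_obs = 20, sd_animal = 0)
  fit <- suppressWarnings(
    fit_activity_lmm(d, temperature_as = "numeric"))
  ols <- stats::lm(value ~ temperature * co2_level, data = d)
  expect_equal(fit$fixed$estimate, unname(stats::coef(ols)),
               tolerance = 1e-4)
})

test_that("mixed model recovers simulated slope and variance components", {
  set.seed(201)
  d <- sim_lmm_data(n_animals = 8, n_obs = 50, beta_t = 0.5,
                    sd_animal = 1, sd_e = 0.5)
  d$temperature <- (d$temperature - 12) / 2 # per-step coding
  fit <- fit_activity_lmm(d, temperature_as = "numeric")
  i <- match("temperature", fit$fixed$term)
  expect_lt(abs(fit$fixed$estimate[i] - 0.5), 2 * fit$fixed$se[i])
  expect_equal(fit$random_intercept_sd, 1, tolerance = 0.35)
  expect_equal(fit$residual_sd, 0.5, tolerance = 0.1)
  expect_false(is.null(fit$lrt_interaction$p))
})

test_that("Tukey family correction behaves at the k = 2 boundary and above", {
  set.seed(202)
  d <- sim_lmm_data(n_animals = 4, n_obs = 10)
  d2 <- d[d$temperature %in% c(12, 20) &
            d$co2_level == "normocapnia", ]
  fit2 <- fit_activity_lmm(d2, temperature_as = "factor")
  tk <- tukey_pairwise(fit2)
  expect_equal(nrow(tk), 1L) # two cells -> a single contrast
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))

  fit <- fit_activity_lmm(d)
  tk_all <- tukey_pairwise(fit)
  expect_equal(nrow(tk_all), choose(10, 2))
  raw <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit$model, ~ temperature * co2_level),
    method = "pairwise", adjust = "none"))
  expect_true(all(tk_all$p_adj >= raw$p.value - 1e-12))
})

test_that("identical group means produce no Tukey rejections", {
  set.seed(203)
  d <- sim_lmm_data(n_animals = 6, n_obs = 40, beta_t = 0, sd_animal = 0.5)
  fit <- suppressWarnings(fit_activity_lmm(d))
  tk <- tukey_pairwise(fit)
  expect_lt(mean(tk$significant), 0.06)
})

test_that("Kruskal-Wallis H and exact p match enumeration", {
  expect_equal(kruskal_wallis(c(1, 1, 1, 1), c("a", "a", "b", "b"))$H, 0)
  expect_equal(kruskal_wallis(c(1, 1, 1, 1), c("a", "a", "b", "b"))$p, 1)

  res <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$H, 2.4)
  expect_equal(res$p, 1 / 3)
  expect_identical(res$method, "exact")

  # H equals the base implementation on random data (tie-corrected)
  set.seed(204)
  for (rep in 1:20) {
    v <- sample(1:8, 30, replace = TRUE) # plenty of ties
    gr <- sample(c("a", "b", "c"), 30, replace = TRUE)
    ours <- kruskal_wallis(v, gr)
    base <- stats::kruskal.test(v, factor(gr))
    expect_equal(ours$H, unname(base$statistic), tolerance = 1e-10)
    expect_equal(ours$p, base$p.value, tolerance = 1e-10)
  }

  # exact p equals explicit enumeration over label assignments
  set.seed(205)
  for (rep in 1:5) {
    v <- rnorm(7)
    gr <- c("a", "a", "b", "b", "c", "c", "c")
    ours <- kruskal_wallis(v, gr)
    combos <- utils::combn(7, 2)
    hs <- c()
    for (i in seq_len(ncol(combos))) {
      rest <- setdiff(1:7, combos[, i])
      inner <- utils::combn(rest, 2)
      for (j in seq_len(ncol(inner))) {
        lab <- rep("c", 7)
        lab[combos[, i]] <- "a"
        lab[inner[, j]] <- "b"
        hs <- c(hs, unname(stats::kruskal.test(v, factor(lab))$statistic))
      }
    }
    expect_equal(ours$p, mean(hs >= ours$H - 1e-12), tolerance = 1e-12)
  }
})

test_that("Tamhane T2 reduces to Welch and stays conservative", {
  set.seed(206)
  a <- rnorm(10); b <- rnorm(12, sd = 3)
  t2 <- tamhane_t2(c(a, b), rep(c("a", "b"), c(10, 12)))
  welch <- stats::t.test(a, b)
  expect_equal(t2$p_adj, welch$p.value, tolerance = 1e-12)

  v <- rnorm(30); gr <- rep(c("a", "b", "c"), 10)
  t3 <- tamhane_t2(v, gr)
  expect_true(all(t3$p_adj >= t3$p_raw))
  expect_warning(
    t2w <- tamhane_t2(c(rnorm(5), rnorm(5), 1),
                      rep(c("a", "b", "c"), c(5, 5, 1))),
    "excluded")
  expect_equal(nrow(t2w), 1L)

  # conservative family-wise error under the null
  set.seed(207)
  rejections <- replicate(300, {
    any(tamhane_t2(rnorm(30), rep(c("a", "b", "c"), each = 10))$significant)
  })
  expect_lt(mean(rejections), 0.08)
})

test_that("Wilcoxon rank-sum matches exhaustive permutation", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 1 / 3)

  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # permutation oracle on random small samples
  set.seed(208)
  for (rep in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    ours <- wilcoxon_rank_sum(a, b)
    pool <- c(a, b)
    combos <- utils::combn(8, 4)
    u_obs <- sum(rank(pool)[1:4]) - 4 * 5 / 2
    us <- apply(combos, 2, function(ix) sum(rank(pool)[ix]) - 10)
    # two-sided: distance from the mean U = n1 n2 / 2
    p_perm <- mean(abs(us - 8) >= abs(u_obs - 8) - 1e-12)
    expect_equal(ours$p, p_perm, tolerance = 1e-10)
  }

  # invariance under strictly monotone transforms
  set.seed(209)
  a <- runif(8); b <- runif(6)
  expect_equal(wilcoxon_rank_sum(a, b)$p,
               wilcoxon_rank_sum(exp(a), exp(b))$p)
  expect_equal(kruskal_wallis(c(a, b), rep(1:2, c(8, 6)))$p,
               kruskal_wallis(log(c(a, b)), rep(1:2, c(8, 6)))$p)
})

test_that("Wilcoxon type-I error rate is near nominal", {
  set.seed(210)
  rej <- replicate(2000, wilcoxon_rank_sum(rnorm(8), rnorm(8))$p < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
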