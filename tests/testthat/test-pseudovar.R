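numeric_minimizer <- function(fm, sm, ft, st, delta = 0.25, upper = 50) {
  obj <- function(a) {
    (modified_z(fm, sm + a, delta) - modified_z(ft, st, delta))^2
  }
  opt <- stats::optimize(obj, c(0, upper), tol = 1e-10)
  # the constrained minimum can sit at the boundary
  if (obj(0) <= opt$objective) 0 else opt$minimum
}

test_that("closed-form alpha equals the numeric minimizer of the z-matching objective", {
  expect_equal(alpha_same_sign(1.0, 0.5, 0.5, 0.5), 0.5)
  expect_equal(alpha_same_sign(0.8, 0.4, 0.8, 0.4), 0)
  expect_equal(alpha_same_sign(0.3, 1.0, 0.9, 0.3), 0)  # clip active

  set.seed(52)
  for (i in 1:200) {
    fm <- rnorm(1, 0, 1.5)
    ft <- sign(fm) * abs(rnorm(1, 0, 1.5))
    sm <- runif(1, 0.05, 1.5)
    st <- runif(1, 0.05, 1.5)
    expect_equal(alpha_same_sign(fm, sm, ft, st),
                 numeric_minimizer(fm, sm, ft, st), tolerance = 1e-6)
  }
  expect_error(alpha_same_sign(1, 0, 1, 1), "degenerate")
})

test_that("alpha_same_sign is monotone in the two z-scores", {
  # nondecreasing in z_m (through |f_m|), nonincreasing in z_t
  a0 <- alpha_same_sign(1.0, 0.5, 0.8, 0.5)
  expect_gte(alpha_same_sign(1.5, 0.5, 0.8, 0.5), a0)
  expect_lte(alpha_same_sign(1.0, 0.5, 1.2, 0.5), a0)
})

test_that("imputation model recovers exactly linear training data", {
  set.seed(61)
  n <- 80
  tr <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:n),
    f_m = runif(n, 1, 3),
    s_m = runif(n, 0.2, 0.6),
    f_t = runif(n, 0.1, 0.3),
    s_t = runif(n, 0.2, 0.8)
  )
  zm <- modified_z(tr$f_m, tr$s_m)
  zt <- modified_z(tr$f_t, tr$s_t)
  stopifnot(all(zm > zt))
  alphas <- exp(1 + 2 * log(zm - zt) + 0.5 * tr$s_m - 0.3 * tr$s_t)
  fit <- suppressWarnings(fit_imputation_model(tr, alphas))
  expect_equal(unname(fit$coef), c(1, 2, 0.5, -0.3), tolerance = 1e-8)
  expect_equal(fit$n_fit, n)
  expect_lt(fit$sigma, 1e-10)

  # independent oracle: normal-equations solve
  X <- cbind(1, log(zm - zt), tr$s_m, tr$s_t)
  beta <- solve(t(X) %*% X, t(X) %*% log(alphas))
  expect_equal(unname(fit$coef), as.numeric(beta), tolerance = 1e-8)
})

test_that("constant pseudo variances give a flat model at log(c)", {
  tr <- make_training(n = 50, seed = 62)
  fit <- suppressWarnings(fit_imputation_model(tr, rep(0.7, 50)))
  expect_equal(unname(fit$coef), c(log(0.7), 0, 0, 0), tolerance = 1e-10)
})

test_that("realistic synthetic training shows a positive log-linear association", {
  study <- suppressMessages(
    generate_paired_study(synthetic_config(n_genes = 3000, seed = 63))
  )
  paired <- suppressMessages(
    join_orthologs(study$model_train, study$target_train,
                   study$ortholog_map)
  )
  concordant <- sign(paired$f_m) == sign(paired$f_t)
  alphas <- rep(NA_real_, nrow(paired))
  alphas[concordant] <- alpha_same_sign(
    paired$f_m[concordant], paired$s_m[concordant],
    paired$f_t[concordant], paired$s_t[concordant]
  )
  fit <- fit_imputation_model(paired, alphas)
  expect_gt(fit$coef[["log_zdiff"]], 0)
})

test_that("too few positive alphas raise a training-insufficient error naming the count", {
  tr <- make_training(n = 20, seed = 64)
  expect_error(fit_imputation_model(tr, rep(0, 20)), "only 0")
})

test_that("opposite-sign imputation follows the fitted model on the summed z magnitudes", {
  forced <- structure(
    list(coef = c(intercept = 0, log_zdiff = 1, s_m = 0, s_t = 0),
         n_fit = 10L, sigma = 0, r_squared = 1, delta = 0.25),
    class = "ebt_imputation_model"
  )
  # z_m = z_t = 1 -> predictor log(2) -> alpha = 2
  expect_equal(alpha_opposite_sign(0.5, 0.5, -0.5, 0.5, forced), 2)

  tiny <- forced
  tiny$coef[["intercept"]] <- -50
  tiny$coef[["log_zdiff"]] <- 0
  a <- alpha_opposite_sign(1, 0.5, -1, 0.5, tiny)
  expect_gt(a, 0)                      # no clip: always positive on log scale
  expect_lt(a, 1e-20)

  expect_error(alpha_opposite_sign(1, 0.5, -1, 0.5, model = NULL),
               "fit the imputation model")
})

test_that("training routes genes by sign concordance and records provenance", {
  tr <- make_training(n = 400, frac_discordant = 0.3, seed = 65)
  pv <- suppressMessages(train_pseudo_variances(tr))
  expect_true(all(pv$alpha >= 0))
  observed_disc <- sign(tr$f_m) != sign(tr$f_t) &
    sign(tr$f_m) != 0 & sign(tr$f_t) != 0
  expect_equal(pv$provenance == "imputed", unname(observed_disc))

  # discordant genes carry heavier penalties than concordant ones
  expect_gt(median(pv$alpha[pv$provenance == "imputed"]),
            median(pv$alpha[pv$provenance == "direct"]))

  g <- glance(pv)
  expect_equal(g$n_genes, 400)
  expect_equal(g$n_alpha_zero + g$n_alpha_moderate + g$n_alpha_large, 400)
})

test_that("a perfect training pair yields all-zero alphas and no imputation", {
  tr <- make_training(n = 50, seed = 66)
  tr$f_t <- tr$f_m
  tr$s_t <- tr$s_m
  pv <- suppressMessages(train_pseudo_variances(tr))
  expect_true(all(pv$alpha == 0))
  expect_true(all(pv$provenance == "direct"))
  expect_null(attr(pv, "imputation_model"))
})

test_that("training is invariant to gene order", {
  tr <- make_training(n = 300, frac_discordant = 0.25, seed = 67)
  pv1 <- suppressMessages(train_pseudo_variances(tr))
  perm <- sample(nrow(tr))
  pv2 <- suppressMessages(train_pseudo_variances(tr[perm, ]))
  m <- match(pv1$gene_id, pv2$gene_id)
  expect_equal(pv1$alpha, pv2$alpha[m], tolerance = 1e-10)
})

test_that("penalized training z-scores match the target exactly where alpha > 0", {
  tr <- make_training(n = 300, seed = 68)
  pv <- suppressMessages(train_pseudo_variances(tr))
  direct <- pv$provenance == "direct"
  zt <- modified_z(tr$f_t, tr$s_t)
  z_pen <- modified_z(tr$f_m, tr$s_m + pv$alpha)
  pos <- direct & pv$alpha > 0
  expect_equal(z_pen[pos], zt[pos], tolerance = 1e-9)
  expect_true(all(z_pen[direct & pv$alpha == 0] <= zt[direct & pv$alpha == 0] + 1e-12))
})

test_that("pseudo-variance tables round-trip losslessly through disk", {
  tr <- make_training(n = 200, frac_discordant = 0.2, seed = 69)
  pv <- suppressMessages(train_pseudo_variances(tr))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pseudovar(pv, path)
  back <- read_pseudovar(path)
  expect_equal(back$gene_id, pv$gene_id)
  expect_equal(back$alpha, pv$alpha, tolerance = 1e-13)
  expect_equal(back$provenance, pv$provenance)
  m1 <- attr(pv, "imputation_model")
  m2 <- attr(back, "imputation_model")
  expect_equal(m1$coef, m2$coef, tolerance = 1e-13)
  expect_equal(attr(back, "delta"), 0.25)
})
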