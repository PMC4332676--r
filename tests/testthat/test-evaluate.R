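fake_results <- function(gene_id, p, t = NULL, f = NULL) {
  tibble::tibble(
    gene_id = gene_id,
    p = p,
    t = if (is.null(t)) -stats::qnorm(p / 2) else t,
    f = if (is.null(f)) rep(1, length(gene_id)) else f,
    direction = sign(if (is.null(f)) rep(1, length(gene_id)) else f)
  )
}

test_that("selection rules pick by threshold and by deterministic top-n", {
  res <- fake_results(paste0("g", 1:4), p = c(0.01, 0.2, 0.03, 0.9))
  expect_setequal(select_genes(res, "p_threshold", theta = 0.05),
                  c("g1", "g3"))
  expect_equal(select_genes(res, "top_n", k = 2), c("g1", "g3"))

  # ties on p broken by larger |t|, then gene id
  tied <- fake_results(c("a", "b", "c"), p = c(0.5, 0.5, 0.5),
                       t = c(3, 5, 5))
  expect_equal(select_genes(tied, "top_n", k = 1), "b")
  expect_equal(select_genes(tied, "top_n", k = 2), c("b", "c"))
  expect_warning(all_g <- select_genes(tied, "top_n", k = 10), "universe")
  expect_equal(length(all_g), 3)
})

test_that("overall agreement counts matched nonzero directions only", {
  model <- tibble::tibble(gene_id = paste0("g", 1:4),
                          direction = c(1, 1, -1, -1))
  target <- tibble::tibble(gene_id = paste0("g", 1:4),
                           direction = c(1, -1, -1, -1))
  rep <- overall_agreement(paste0("g", 1:4), model, target)
  expect_equal(rep$fraction, 0.75)
  expect_equal(rep$layer, "overall")

  expect_equal(overall_agreement(paste0("g", 1:4), model, model)$fraction, 1)

  # zero directions stay in the denominator as disagreements
  tz <- target
  tz$direction[1] <- 0
  expect_equal(overall_agreement(paste0("g", 1:4), model, tz)$fraction, 0.5)

  expect_warning(empty <- overall_agreement(character(), model, target),
                 "empty selection")
  expect_equal(empty$n_selected, 0)
  expect_true(is.na(empty$fraction))
})

test_that("random target directions give ~50% overall agreement", {
  set.seed(81)
  n <- 10000
  ids <- sprintf("g%05d", 1:n)
  model <- tibble::tibble(gene_id = ids,
                          direction = sample(c(-1, 1), n, replace = TRUE))
  target <- tibble::tibble(gene_id = ids,
                           direction = sample(c(-1, 1), n, replace = TRUE))
  expect_equal(overall_agreement(ids, model, target)$fraction, 0.5,
               tolerance = 0.02)
})

test_that("experiment-specific agreement requires a matching flip on both sides", {
  tab <- function(d) tibble::tibble(gene_id = c("g1", "g2", "g3"),
                                    direction = d)
  # g1: model flips + -> -, target flips + -> -      => specific, agreed
  # g2: model flips + -> -, target stays -            => specific, not agreed
  # g3: model does not flip                           => not specific
  rep <- specific_response_agreement(
    c("g1", "g2", "g3"),
    model_train = tab(c(1, 1, 1)), model_test = tab(c(-1, -1, 1)),
    target_train = tab(c(1, -1, 1)), target_test = tab(c(-1, -1, 1))
  )
  expect_equal(rep$n_selected, 2)
  expect_equal(rep$n_agree, 1)
  expect_equal(rep$fraction, 0.5)

  # identical experiments on both axes: nothing is specific
  same <- specific_response_agreement(
    c("g1", "g2", "g3"),
    tab(c(1, -1, 1)), tab(c(1, -1, 1)), tab(c(1, -1, 1)), tab(c(1, -1, 1))
  )
  expect_equal(same$n_selected, 0)
})

test_that("fisher enrichment matches the exact hypergeometric tail oracle", {
  universe <- paste0("g", 1:100)
  selected <- paste0("g", 1:10)
  sets <- list(
    hit = c(paste0("g", 1:5), paste0("g", 51:55)),  # 5 of 10 selected
    cold = paste0("g", 60:69),                       # disjoint from selection
    exact = selected                                 # set == selection
  )
  enr <- fisher_enrichment(selected, universe, sets)
  expect_equal(enr$p[enr$set_name == "hit"],
               hyper_tail_oracle(5, 10, 100, 10))
  expect_equal(enr$p[enr$set_name == "hit"], 6.716277e-4, tolerance = 1e-6)
  expect_gt(enr$p[enr$set_name == "cold"], 0.3)
  expect_equal(enr$p[enr$set_name == "exact"],
               hyper_tail_oracle(10, 10, 100, 10))
  # the all-overlap configuration is the most extreme reachable p
  expect_lt(enr$p[enr$set_name == "exact"], min(enr$p[1:2]))

  # agreement with the standard one-sided Fisher exact test
  ft <- stats::fisher.test(matrix(c(5, 5, 5, 85), nrow = 2),
                           alternative = "greater")
  expect_equal(enr$p[enr$set_name == "hit"], ft$p.value)

  expect_error(fisher_enrichment(selected, character(), sets),
               "configuration error")
})

test_that("context agreement pools activated and suppressed directions", {
  # universe of 1000; model activates g1..g50 and suppresses h1..h50
  universe <- c(paste0("g", 1:500), paste0("h", 1:500))
  model <- tibble::tibble(
    gene_id = universe,
    f = rep(c(1, -1), each = 500),
    p = c(rep(1e-6, 50), rep(0.9, 450), rep(1e-6, 50), rep(0.9, 450))
  )
  # target activates g1..g25 and suppresses h1..h40 only
  target <- tibble::tibble(
    gene_id = universe,
    f = rep(c(1, -1), each = 500),
    p = c(rep(1e-6, 25), rep(0.9, 475), rep(1e-6, 40), rep(0.9, 460))
  )
  sets <- c(
    stats::setNames(lapply(1:10, function(i) paste0("g", (5 * i - 4):(5 * i))),
                    paste0("act", 1:10)),
    stats::setNames(lapply(1:10, function(i) paste0("h", (5 * i - 4):(5 * i))),
                    paste0("sup", 1:10))
  )
  rep <- context_agreement(model, target, sets, theta = 0.05)
  # 5 of 10 activated contexts and 8 of 10 suppressed contexts shared
  expect_equal(rep$n_selected, 20)
  expect_equal(rep$n_agree, 13)
  expect_equal(rep$fraction, 0.65)
  detail <- attr(rep, "detail")
  expect_equal(detail$n_common[detail$direction == "activated"], 5)
  expect_equal(detail$n_common[detail$direction == "suppressed"], 8)

  # identical results agree perfectly
  expect_equal(context_agreement(model, model, sets)$fraction, 1)
})

test_that("the exclusion baseline intersects the three significant lists", {
  ids <- paste0("g", 1:6)
  mk <- function(p) fake_results(ids, p)
  mt <- mk(c(0.01, 0.01, 0.5, 0.01, 0.5, 0.01))
  tt <- mk(c(0.01, 0.5, 0.01, 0.01, 0.5, 0.01))
  te <- mk(c(0.01, 0.01, 0.01, 0.5, 0.5, 0.01))
  expect_setequal(exclusion_baseline(mt, tt, te), c("g1", "g6"))

  none <- mk(rep(0.9, 6))
  expect_equal(length(exclusion_baseline(none, tt, te)), 0)
  all_sig <- mk(rep(0.001, 6))
  expect_setequal(exclusion_baseline(all_sig, all_sig, te),
                  select_genes(te, "p_threshold"))
})

test_that("rank correlation of fold changes behaves at the extremes", {
  a <- tibble::tibble(gene_id = paste0("g", 1:50), f = rnorm(50))
  expect_equal(rank_correlation(a, a), 1)
  b <- a
  b$f <- -a$f
  expect_equal(rank_correlation(a, b), -1)

  set.seed(82)
  big_a <- tibble::tibble(gene_id = paste0("g", 1:5000), f = rnorm(5000))
  big_b <- tibble::tibble(gene_id = paste0("g", 1:5000), f = rnorm(5000))
  expect_equal(rank_correlation(big_a, big_b), 0, tolerance = 0.05)

  const <- tibble::tibble(gene_id = paste0("g", 1:10), f = rep(1, 10))
  expect_warning(r <- rank_correlation(const, a[1:10, ]), "undefined")
  expect_true(is.na(r))
  expect_error(rank_correlation(a[1:2, ], a[1:2, ]), "3 shared genes")
})
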