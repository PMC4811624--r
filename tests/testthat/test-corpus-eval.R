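make_corpus <- function(n_default = 8, n_engineered = 2) {
  c(
    lapply(seq_len(n_default), function(s) {
      generate_gaw(synthetic_gaw_spec(seed = s))$gaw
    }),
    lapply(seq_len(n_engineered) + 100, function(s) {
      # high first-cycle amplitude: the parabola never dips below 32.2% of
      # the saturation amplitude, so its lower crossing does not exist
      generate_gaw(synthetic_gaw_spec(r0_true = 0.5, a_true = 40,
                                      seed = s))$gaw
    })
  )
}

test_that("reliability counts the engineered polynomial failures", {
  recs <- make_corpus()
  cfg <- pipeline_config(variants = "GAW_f", families = c("P2", "P3", "P4"),
                         definitions = "VOT67")
  tab <- evaluate_corpus(recs, cfg)
  rel <- function(fam) tab$reliability[tab$family == fam]
  expect_equal(rel("P2"), 80)
  expect_equal(rel("P4"), 100)
  expect_equal(unique(tab$n), 10)
  expect_true(all(tab$reliability >= 0 & tab$reliability <= 100))
})

test_that("identical recordings have zero VOT spread", {
  g <- generate_gaw(synthetic_gaw_spec(seed = 21))$gaw
  cfg <- pipeline_config(variants = "GAW_f", families = "P4",
                         definitions = "VOT67")
  tab <- evaluate_corpus(list(g, g, g), cfg)
  expect_equal(tab$sd_vot_ms, 0)
  expect_equal(tab$reliability, 100)
})

test_that("row statistics match a brute-force recomputation", {
  recs <- make_corpus(4, 1)
  cfg <- pipeline_config(variants = "GAW_f", families = c("P2", "P4"))
  tab <- evaluate_corpus(recs, cfg)
  per <- lapply(recs, function(r) run_pipeline(r, cfg)$summary)
  for (k in seq_len(nrow(tab))) {
    rows <- do.call(rbind, lapply(per, function(s) {
      s[s$variant == tab$variant[k] & s$family == tab$family[k] &
          s$definition == tab$definition[k], ]
    }))
    expect_equal(tab$reliability[k], 100 * mean(rows$computable))
    if (any(rows$computable)) {
      expect_equal(tab$mean_vot_ms[k], mean(rows$vot_ms[rows$computable]))
      expect_equal(tab$sd_vot_ms[k], sd(rows$vot_ms[rows$computable]))
    }
  }
})

test_that("VOT67 is at least as reliable as VOT90 for each polynomial family", {
  recs <- make_corpus(5, 2)
  cfg <- pipeline_config(variants = "GAW_f", families = c("P2", "P3", "P4"))
  tab <- evaluate_corpus(recs, cfg)
  for (fam in c("P2", "P3", "P4")) {
    r67 <- tab$reliability[tab$family == fam & tab$definition == "VOT67"]
    r90 <- tab$reliability[tab$family == fam & tab$definition == "VOT90"]
    expect_gte(r67, r90)
  }
})

test_that("failed recordings are absorbed, not fatal", {
  good <- generate_gaw(synthetic_gaw_spec(seed = 22))$gaw
  bad <- gaw_signal(abs(rep(c(0.01, 0.02), 50)), fps = 8000)  # no usable cycles
  cfg <- pipeline_config(variants = "GAW_f", families = "P4",
                         definitions = "VOT67")
  tab <- evaluate_corpus(list(good, bad), cfg)
  expect_equal(tab$reliability, 50)
  expect_equal(tab$n, 2)
  # adding a computable recording never decreases reliability
  tab3 <- evaluate_corpus(list(good, bad, good), cfg)
  expect_gte(tab3$reliability, tab$reliability)
})

test_that("corpus mean VOT tracks the generator growth rate", {
  recs <- lapply(1:12, function(s) {
    generate_gaw(synthetic_gaw_spec(a_true = 25, seed = 300 + s))$gaw
  })
  cfg <- pipeline_config(variants = "GAW_o", families = "M_a",
                         definitions = "VOT67")
  tab <- evaluate_corpus(recs, cfg)
  expect_lt(abs(tab$mean_vot_ms - 40) / 40, 0.15)
})

test_that("reporting precision matches the table convention", {
  recs <- make_corpus(3, 0)
  cfg <- pipeline_config(variants = "GAW_f", families = "P4",
                         definitions = "VOT67")
  tab <- format_corpus_table(evaluate_corpus(recs, cfg))
  expect_equal(tab$reliability, round(tab$reliability))
  expect_equal(tab$mean_vot_ms, round(tab$mean_vot_ms))
  expect_equal(tab$mean_rmse, round(tab$mean_rmse, 2))
})
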