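test_that("default config reproduces the published endpoint volumes", {
  cfg <- default_synthetic_config()
  expect_identical(validate_synthetic_config(cfg), cfg)
  expect_equal(cfg$volumes["alcohol", "2012"], 1569)
  expect_equal(cfg$volumes["alcohol", "2016"], 2119)
  expect_equal(cfg$volumes["opioid", c("2012", "2016")], c("2012" = 19, "2016" = 74))
  expect_equal(cfg$volumes["cannabis", c("2012", "2016")], c("2012" = 10, "2016" = 73))
  expect_equal(cfg$volumes["multiple", c("2012", "2016")], c("2012" = 187, "2016" = 453))
  expect_equal(cfg$volumes["substance_other", c("2012", "2016")], c("2012" = 52, "2016" = 160))
  expect_equal(cfg$volumes["NMHA", "2012"], 52422)
  expect_equal(cfg$volumes["NMHA", "2016"], 58947)
  # fiscal-2012/2016 MHA totals equal the published aggregates
  mha <- setdiff(rownames(cfg$volumes), "NMHA")
  expect_equal(sum(cfg$volumes[mha, "2012"]), 3923)
  expect_equal(sum(cfg$volumes[mha, "2016"]), 6131)
  expect_equal(sum(cfg$volumes[, "2016"]), 65078)
  expect_equal(sum(cfg$volumes[, "2012"]), 56345)
})

test_that("default config carries the published LOS means", {
  cfg <- default_synthetic_config()
  expect_true(all(cfg$los_mean["anxiety", ] == 4.0))
  expect_true(all(cfg$los_mean["schizophrenia", ] == 14.4))
  expect_true(all(cfg$los_mean["mood", ] == 12.1))
  expect_true(all(cfg$los_mean["others", ] == 8.9))
  # discharged anchors, with the disposition-weighted mean preserved
  expect_equal(cfg$los_mean["substance", "discharged"], 5.8)
  expect_equal(cfg$los_mean["NMHA", "discharged"], 4.0)
  for (cat_ in c("NMHA", "substance")) {
    target <- c(NMHA = 6.1, substance = 6.2)[[cat_]]
    expect_equal(sum(cfg$los_mean[cat_, ] * cfg$disposition_prob[cat_, ]),
                 target, tolerance = 1e-12)
  }
  # proportion vectors are simplexes
  expect_equal(unname(rowSums(cfg$ctas_prob)), rep(1, 6))
  expect_equal(unname(rowSums(cfg$disposition_prob)), rep(1, 6))
})

test_that("record counts equal configured volumes exactly, per year and stream", {
  h <- fixture_history()
  cfg <- default_synthetic_config()
  expect_equal(nrow(h), sum(cfg$volumes))
  tab <- table(h$fiscal_year, ifelse(h$category == "substance",
                                     ifelse(h$substance_subgroup == "other",
                                            "substance_other",
                                            h$substance_subgroup),
                                     h$category))
  for (yr in cfg$years) {
    for (stream in rownames(cfg$volumes)) {
      expect_equal(unname(tab[yr, stream]), unname(cfg$volumes[stream, yr]))
    }
  }
  # the fiscal-2016 MHA count is exactly the published total
  expect_equal(sum(h$fiscal_year == "2016" & h$category != "NMHA"), 6131)
})

test_that("a zero-volume stream yields no records", {
  cfg <- default_synthetic_config()
  cfg$volumes[, ] <- 0
  cfg$volumes["cannabis", ] <- 5
  h <- generate_visit_history(cfg, seed = 3)
  expect_equal(nrow(h), 25)
  expect_true(all(h$substance_subgroup == "cannabis"))
})

test_that("negative volumes are rejected", {
  cfg <- default_synthetic_config()
  cfg$volumes["mood", "2014"] <- -1
  expect_error(generate_visit_history(cfg, seed = 1), "non-negative")
})

test_that("generation is reproducible under a fixed seed", {
  cfg <- default_synthetic_config()
  cfg$volumes <- cfg$volumes %/% 50  # small copies are enough here
  h1 <- generate_visit_history(cfg, seed = 99)
  h2 <- generate_visit_history(cfg, seed = 99)
  expect_identical(h1, h2)
  h3 <- generate_visit_history(cfg, seed = 100)
  expect_false(identical(h1, h3))
})

test_that("records respect the type invariants and the ICD grouping", {
  h <- fixture_history()
  expect_true(all(h$los_hours > 0))
  expect_true(all(h$ctas %in% 1:5))
  expect_identical(h$substance_subgroup != "none", h$category == "substance")
  idx <- seq(1, nrow(h), by = 37) # thinned re-check against the grouper
  m <- categorize_icd(h$icd_code[idx])
  expect_equal(m$category, h$category[idx])
  expect_equal(m$substance_subgroup, h$substance_subgroup[idx])
  # timestamps live inside their fiscal year (8,760 h blocks from epoch)
  yr_idx <- as.integer(h$fiscal_year) - 2012L
  expect_true(all(h$arrival_time >= yr_idx * 8760 &
                    h$arrival_time <= (yr_idx + 1) * 8760))
})

test_that("sampled LOS, CTAS and dispositions track the configuration", {
  h <- fixture_history()
  cfg <- default_synthetic_config()
  # schizophrenia mean LOS within 3 standard errors of 14.4 h
  scz <- h$los_hours[h$category == "schizophrenia"]
  se <- sd(scz) / sqrt(length(scz))
  expect_lt(abs(mean(scz) - 14.4), 3 * se)
  # CTAS and disposition mixes pass a chi-square GOF at alpha = 0.01
  nm <- h[h$category == "NMHA" & h$fiscal_year == "2016", ]
  expect_gt(chisq.test(tabulate(nm$ctas, 5),
                       p = cfg$ctas_prob["NMHA", ])$p.value, 0.01)
  disp_counts <- table(factor(nm$disposition,
                              levels = colnames(cfg$disposition_prob)))
  expect_gt(chisq.test(as.numeric(disp_counts),
                       p = cfg$disposition_prob["NMHA", ])$p.value, 0.01)
})

test_that("visit histories round-trip through CSV", {
  cfg <- default_synthetic_config()
  cfg$volumes <- cfg$volumes %/% 200
  h <- generate_visit_history(cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_visit_history(h, path)
  back <- read_visit_history(path)
  expect_equal(back, h, tolerance = 1e-12)
})
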