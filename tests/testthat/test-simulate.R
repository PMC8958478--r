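test_that("identical configs and seeds yield identical cohorts", {
  cfg <- generator_config(n_practices = 8, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # extending the cohort leaves earlier practices untouched
  cfg2 <- generator_config(n_practices = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg2)
  expect_identical(a$practices, b$practices[1:8])
})

test_that("deterministic limits of the tie model hold", {
  full <- generate_cohort(generator_config(n_practices = 5, tie_prob = 1,
                                           retention = c(CHD = 1, CHF = 1),
                                           nonresponse_prob = 0, seed = 2))
  met <- cohort_metrics(full)
  expect_true(all(met$density == 1))
  expect_true(all(met$reciprocity == 1))

  none <- generate_cohort(generator_config(n_practices = 5, tie_prob = 0,
                                           nonresponse_prob = 0, seed = 2))
  for (pr in none$practices) {
    for (cn in CONDITIONS) {
      expect_equal(nrow(build_directed_network(pr, cn)$ties), 0)
    }
  }

  # full retention: CHF tie set identical to DM tie set
  keepall <- generate_cohort(generator_config(n_practices = 5, tie_prob = 0.5,
                                              retention = c(CHD = 1, CHF = 1),
                                              nonresponse_prob = 0, seed = 3))
  for (pr in keepall$practices) {
    dm <- build_directed_network(pr, "DM")$ties
    chf <- build_directed_network(pr, "CHF")$ties
    expect_identical(dm, chf)
  }
})

tie_key <- function(ties) paste(ties$from, ties$to)

test_that("condition tie sets are nested: CHF within CHD within DM", {
  coh <- generate_cohort(generator_config(n_practices = 30, seed = 17))
  for (pr in coh$practices) {
    dm <- tie_key(build_directed_network(pr, "DM")$ties)
    chd <- tie_key(build_directed_network(pr, "CHD")$ties)
    chf <- tie_key(build_directed_network(pr, "CHF")$ties)
    expect_true(all(chd %in% dm))
    expect_true(all(chf %in% chd))
  }
})

test_that("the closed-form edge probability matches its trivial limits", {
  expect_equal(expected_edge_probability(
    generator_config(tie_prob = 1, nonresponse_prob = 0), "DM"), 1)
  expect_equal(expected_edge_probability(
    generator_config(tie_prob = 0, nonresponse_prob = 0), "DM"), 0)
  # p = 0.5, r = 0: independent directions, union rule
  expect_equal(expected_edge_probability(
    generator_config(tie_prob = 0.5, recip_boost = 0, nonresponse_prob = 0),
    "DM"), 0.75)
  expect_error(expected_edge_probability(
    generator_config(nonresponse_prob = 0.1), "DM"), "no closed form")
  expect_error(expected_edge_probability(
    generator_config(hub_bias = 2, hub_fraction = 1, nonresponse_prob = 0),
    "DM"), "no closed form")
})

test_that("empirical density matches the closed form within 3 standard errors", {
  cfg <- generator_config(n_practices = 1500, tie_prob = 0.45,
                          recip_boost = 0.25, nonresponse_prob = 0, seed = 21)
  met <- cohort_metrics(generate_cohort(cfg))
  for (cn in CONDITIONS) {
    sub <- met[met$condition == cn, ]
    n_pairs <- sum(sub$n_nodes * (sub$n_nodes - 1) / 2)
    p_hat <- sum(sub$n_edges) / n_pairs
    p_exp <- expected_edge_probability(cfg, cn)
    se <- sqrt(p_exp * (1 - p_exp) / n_pairs)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
})

test_that("reciprocity increases monotonically in the reciprocation boost", {
  recip_at <- function(r) {
    coh <- generate_cohort(generator_config(n_practices = 150, tie_prob = 0.4,
                                            recip_boost = r,
                                            nonresponse_prob = 0, seed = 31))
    cohort_reciprocity(coh)$reciprocity
  }
  vals <- vapply(c(0, 0.4, 0.8), recip_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("invalid configurations are rejected before any draw", {
  expect_error(generator_config(tie_prob = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(size_range = c(1, 7)), "size_range")
  expect_error(generator_config(size_range = c(7, 3)), "size_range")
  expect_error(generator_config(hub_bias = 0.5), "hub_bias")
  expect_error(generator_config(retention = c(CHD = 0.5)), "retention")
  expect_error(generator_config(n_practices = 0), "n_practices")
})

test_that("independent retention mode breaks the nesting by design", {
  cfg <- generator_config(n_practices = 40, tie_prob = 0.5,
                          retention = "independent", nonresponse_prob = 0,
                          seed = 41)
  coh <- generate_cohort(cfg)
  nested <- vapply(coh$practices, function(pr) {
    dm <- tie_key(build_directed_network(pr, "DM")$ties)
    chf <- tie_key(build_directed_network(pr, "CHF")$ties)
    all(chf %in% dm)
  }, logical(1))
  expect_false(all(nested))
  expect_equal(expected_edge_probability(cfg, "CHF"), 0.75)
})

test_that("calibration covers the four types and rejects unmapped combos", {
  for (bands in list(c("high", "low"), c("medium", "medium"),
                     c("medium", "low"), c("low", "low"))) {
    cfg <- calibrate_to_bands(bands[1], bands[2], n_practices = 10)
    expect_s3_class(cfg, "praxnet_config")
  }
  expect_error(calibrate_to_bands("high", "high"), "no calibrated")
  expect_error(calibrate_to_bands("medium", "high"), "no calibrated")
})

test_that("B and C calibrations put the band medians in their targets", {
  labs <- function(cfg) {
    classify_networks(cohort_metrics(generate_cohort(cfg)))
  }
  lb <- labs(calibrate_to_bands("medium", "medium", n_practices = 200,
                                seed = 7))
  lc <- labs(calibrate_to_bands("medium", "low", n_practices = 200, seed = 7))
  for (cn in CONDITIONS) {
    b <- lb[lb$condition == cn, ]
    expect_equal(band_of(stats::median(b$density)), "medium")
    expect_equal(band_of(stats::median(b$centralization)), "medium")
    c_ <- lc[lc$condition == cn, ]
    expect_equal(band_of(stats::median(c_$density)), "medium")
    expect_equal(band_of(stats::median(c_$centralization)), "low")
    # the target type is also the modal type
    expect_equal(names(which.max(table(b$network_type))), "B")
    expect_equal(names(which.max(table(c_$network_type))), "C")
  }
})
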