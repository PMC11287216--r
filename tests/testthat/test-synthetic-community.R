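test_that("generation is reproducible for a fixed seed", {
  a <- generate_community(seed = 42)
  b <- generate_community(seed = 42)
  expect_identical(a, b)
  c <- generate_community(seed = 43)
  expect_false(identical(a$ani, c$ani))
})

test_that("per-depth read fractions sum to 100 exactly", {
  com <- generate_community(seed = 3)
  sums <- tapply(com$mags$read_fraction_pct, com$mags$depth_cm, sum)
  expect_equal(as.numeric(sums), rep(100, 3), tolerance = 1e-9)
})

test_that("within-OTU symmetrized ANI exceeds the threshold by design", {
  com <- generate_community(seed = 8)
  sym <- symmetrize_ani(com$ani)
  same <- outer(com$mags$otu_id, com$mags$otu_id, "==")
  diag(same) <- FALSE
  expect_true(all(sym[same] > 95))
  expect_true(all(sym[!same & upper.tri(same)] < 95))
})

test_that("marker retention frequency tracks completeness", {
  cfg <- scenario_config(completeness_distribution = c(mean = 80, sd = 0),
                         contamination_distribution = c(mean = 0, sd = 0))
  com <- generate_community(cfg, seed = 12)
  templates <- guild_templates()
  slots <- 0L; hits <- 0L
  for (i in seq_len(nrow(com$mags))) {
    tmpl <- templates[[com$mags$guild[i]]]
    slots <- slots + length(tmpl)
    hits <- hits + sum(tmpl %in% com$mags$markers[[i]])
  }
  p_hat <- hits / slots
  se <- sqrt(0.8 * 0.2 / slots)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("without dropout the classifier recovers every planted guild", {
  cfg <- scenario_config(completeness_distribution = c(mean = 100, sd = 0),
                         contamination_distribution = c(mean = 0, sd = 0))
  com <- generate_community(cfg, seed = 5)
  prof <- profile_from_community(com)
  expect_identical(otus_partition(prof$otus),
                   canonical_partition(split(com$truth$membership$mag_id,
                                             com$truth$membership$otu_id)))
  key <- vapply(prof$otus$members, `[`, "", 1)
  truth_of <- com$truth$membership$otu_id[match(key,
                                                com$truth$membership$mag_id)]
  planted <- com$truth$otus[match(truth_of, com$truth$otus$otu_id), ]
  expect_identical(prof$calls$oxygen_class, planted$oxygen_class)
  expect_identical(prof$calls$carbon_class, planted$carbon_class)
  expect_identical(lapply(prof$calls$pathways, sort),
                   lapply(planted$pathways, sort))
  expect_identical(lapply(prof$calls$donors, sort),
                   lapply(planted$donors, sort))
  expect_identical(lapply(prof$calls$acceptors, sort),
                   lapply(planted$acceptors, sort))
})

test_that("infeasible configurations are rejected", {
  bad_mix <- default_guild_mixture()
  bad_mix[1, 1] <- 0.9
  expect_error(scenario_config(guild_mixture_by_depth = bad_mix),
               "sum to 1")
  expect_error(scenario_config(n_otus = 3), "at least")
  expect_error(scenario_config(ani_within = c(mean = 96, sd = 1)),
               "separated")
})

test_that("porewater emission is deterministic and follows the gradients", {
  pw <- make_porewater(c(0, 5, 30), co2_0 = 300, co2_slope = -4)
  expect_equal(pw$co2_uM, 300 - 4 * c(0, 5, 30))
  flat <- make_porewater(c(0, 5, 30), ph_slope = 0, co2_slope = 0,
                         dpm_slope = 0)
  expect_true(all(vapply(flat[, -1], function(x) length(unique(x)) == 1,
                         logical(1))))
  zero <- make_porewater(dpm0 = 0)
  expect_true(all(normalize_rates(zero)$rate_nmol_per_gdws_h == 0))
  expect_error(make_porewater(c(0, 100), co2_slope = -4), "negative")
})

test_that("guild templates exercise distinct rule paths", {
  calls <- lapply(guild_templates(), call_guild, catalog = load_catalog())
  combos <- vapply(calls, function(cl) {
    paste(cl$oxygen_class, cl$carbon_class,
          paste(sort(cl$pathways), collapse = "+"))
  }, "")
  expect_identical(anyDuplicated(combos), 0L)
})
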