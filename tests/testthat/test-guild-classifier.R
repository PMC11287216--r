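cat_default <- load_catalog()

test_that("pathway detection requires the full diagnostic marker set", {
  expect_identical(detect_pathways(c("RuBisCO", "PRK"), cat_default), "CBB")
  expect_identical(detect_pathways("CODH_ACS", cat_default), character(0))
  expect_identical(detect_pathways(c("CODH_ACS", "FHS"), cat_default), "WL")
  expect_identical(detect_pathways("RuBisCO", cat_default), character(0))
  # rTCA fires on either citrate-cleavage system
  expect_identical(detect_pathways("ACLY", cat_default), "rTCA")
  expect_identical(detect_pathways(c("ccs", "cit"), cat_default), "rTCA")
  expect_identical(detect_pathways("ccs", cat_default), character(0))
  # unknown markers are ignored
  expect_identical(detect_pathways(c("RuBisCO", "PRK", "NotAMarker"),
                                   cat_default), "CBB")
})

test_that("the 3HP family rules and the DC/4HB differential behave", {
  hp3 <- c("PCC", "MCR", "MCL", "ACC")
  expect_identical(detect_pathways(hp3, cat_default), "HP3")
  expect_setequal(detect_pathways(c(hp3, "BUDH"), cat_default),
                  c("HP3", "HP3HB4"))
  # DC/4HB fires on 4-BUDH + pyruvate synthase while 3HP is incomplete
  expect_identical(detect_pathways(c("BUDH", "POR"), cat_default), "DC4HB")
  expect_true("DC4HB" %in% low_confidence_pathways(cat_default))
  # completing the 3HP set converts the differential into 3HP/4HB
  full <- detect_pathways(c(hp3, "BUDH", "POR"), cat_default)
  expect_false("DC4HB" %in% full)
  expect_true(all(c("HP3", "HP3HB4") %in% full))
})

test_that("oxygen classification follows the terminal-oxidase hierarchy", {
  expect_identical(classify_oxygen("Cox", cat_default), "aerobe")
  expect_identical(classify_oxygen("Cyd", cat_default),
                   "aerotolerant_anaerobe")
  expect_identical(classify_oxygen(character(), cat_default), "anaerobe")
  expect_identical(classify_oxygen(c("Cox", "Cyd"), cat_default), "aerobe")
})

test_that("carbon classification distinguishes the four trophic classes", {
  sets <- sedguilds:::central_sets(cat_default)
  central <- unlist(sets)
  wl <- c("CODH_ACS", "FHS")

  m1 <- c(wl, central)
  expect_identical(classify_carbon(m1, detect_pathways(m1, cat_default),
                                   cat_default), "facultative_autotroph")
  expect_identical(classify_carbon(wl, detect_pathways(wl, cat_default),
                                   cat_default), "autotroph")
  ferm <- c(sets$glycolysis, "FeFe")
  expect_identical(classify_carbon(ferm, character(), cat_default),
                   "fermenter")
  het <- c("Cox", sets$glycolysis, sets$tca)
  expect_identical(classify_carbon(het, character(), cat_default),
                   "heterotroph")
  # an oxidase vetoes the fermenter call even with evolving hydrogenases
  expect_identical(classify_carbon(c(ferm, "Cyd"), character(), cat_default),
                   "heterotroph")
  # uptake-only hydrogenase does not make a fermenter
  expect_identical(classify_carbon(c(sets$glycolysis, "NiFe-1a"),
                                   character(), cat_default), "heterotroph")
})

test_that("allow_missing relaxes central-set completeness", {
  sets <- sedguilds:::central_sets(cat_default)
  near <- c("CODH_ACS", "FHS", unlist(sets)[-1])  # one central marker absent
  p <- detect_pathways(near, cat_default)
  expect_identical(classify_carbon(near, p, cat_default), "autotroph")
  expect_identical(classify_carbon(near, p, cat_default, allow_missing = 1),
                   "facultative_autotroph")
})

test_that("donor/acceptor repertoires match described genome contents", {
  # sulfur-oxidizing facultative autotroph: H2/HS-/S2O3 oxidation coupled
  # to O2 or S0 reduction
  da <- donor_acceptor_profile(c("NiFe-1a", "Sqo", "Sox", "SreABC", "Cox"),
                               cat_default)
  expect_setequal(da$donors, c("H2", "sulfide", "thiosulfate"))
  expect_setequal(da$acceptors, c("O2", "S0_polysulfide"))
  # hydrogenotrophic sulfate reducer
  da2 <- donor_acceptor_profile(c("NiFe-1c", "Sat", "AprAB", "DsrAB"),
                                cat_default)
  expect_identical(da2$donors, "H2")
  expect_identical(da2$acceptors, "sulfate")
  # sulfate reduction needs the full Sat+AprAB+DsrAB trio
  da3 <- donor_acceptor_profile(c("Sat", "AprAB"), cat_default)
  expect_length(da3$acceptors, 0)
  da4 <- donor_acceptor_profile(character(), cat_default)
  expect_length(da4$donors, 0)
  expect_length(da4$acceptors, 0)
  expect_identical(donor_acceptor_profile("McrA", cat_default)$acceptors,
                   "CO2_methanogenesis")
})

test_that("OTU calls use union-of-members evidence", {
  # presence in any member dominates absence in another
  call <- call_otu_guild(list(m1 = character(), m2 = "Cox"), cat_default)
  expect_identical(call$oxygen_class, "aerobe")
  expect_identical(call$evidence$Cox, "m2")
  # the union completes a conjunction split across members
  call2 <- call_otu_guild(list(m1 = "RuBisCO", m2 = "PRK"), cat_default)
  expect_identical(call2$pathways, "CBB")
  # single-member OTU equals the member call
  mk <- c("CODH_ACS", "FHS", "NiFe-1a")
  single <- call_otu_guild(list(only = mk), cat_default)
  direct <- call_guild(mk, cat_default)
  expect_identical(single[names(direct)], direct)
  expect_error(call_otu_guild(list(), cat_default), "no member")
})

test_that("identical marker sets always yield identical calls", {
  set.seed(31)
  vocab <- cat_default$markers$marker_id
  for (i in 1:20) {
    mk <- sample(vocab, sample(0:20, 1))
    expect_identical(call_guild(mk, cat_default),
                     call_guild(sample(mk), cat_default))
  }
})

test_that("the rule engine is monotone in presence evidence", {
  # adding a marker never removes a pathway (DC/4HB differential aside),
  # donor, or acceptor
  set.seed(1234)
  vocab <- cat_default$markers$marker_id
  diff_rules <- low_confidence_pathways(cat_default)
  for (i in 1:200) {
    mk <- sample(vocab, sample(0:25, 1))
    extra <- sample(setdiff(vocab, mk), 1)
    before <- call_guild(mk, cat_default)
    after <- call_guild(c(mk, extra), cat_default)
    expect_true(all(setdiff(before$pathways, diff_rules) %in% after$pathways))
    expect_true(all(before$donors %in% after$donors))
    expect_true(all(before$acceptors %in% after$acceptors))
  }
})

test_that("guild sensitivity does not improve as completeness degrades", {
  recovery <- function(mean_completeness, sd, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- scenario_config(
        completeness_distribution = c(mean = mean_completeness, sd = sd),
        contamination_distribution = c(mean = 0, sd = 0)
      )
      com <- generate_community(cfg, seed = s)
      prof <- profile_from_community(com)
      truth <- com$truth$otus
      # planted OTU ids map to recovered ids via shared members
      part_ok <- identical(otus_partition(prof$otus),
                           canonical_partition(split(
                             com$truth$membership$mag_id,
                             com$truth$membership$otu_id)))
      if (!part_ok) return(NA_real_)
      key <- vapply(prof$otus$members, `[`, "", 1)
      truth_of <- com$truth$membership$otu_id[match(key,
                                                    com$truth$membership$mag_id)]
      planted <- truth[match(truth_of, truth$otu_id), ]
      mean(prof$calls$oxygen_class == planted$oxygen_class &
             prof$calls$carbon_class == planted$carbon_class)
    }, numeric(1)), na.rm = TRUE)
  }
  hi <- recovery(98, 1, seeds = 101:103)
  lo <- recovery(60, 4, seeds = 101:103)
  expect_gte(hi, lo - 0.05)   # sampling-error slack
  expect_gte(hi, 0.9)
})
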