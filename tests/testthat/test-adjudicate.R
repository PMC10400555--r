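ref <- demo_label_reference()

mini_products <- function(labels, groups = "sharks_rays") {
  n <- length(labels)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             state = "WA", outlet_type = "fishmonger",
             seafood_group = rep_len(groups, n), origin = "domestic",
             label_main = labels, label_max_detail = labels,
             vendor_claim = NA_character_, price_per_kg = 20,
             stringsAsFactors = FALSE)
}

mini_calls <- function(species) {
  data.frame(sample_id = sprintf("s%02d", seq_along(species)),
             status = ifelse(is.na(species), "no_hits", "assigned"),
             species = species, supporting_hits = 5L, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

test_that("regime-dependent flake adjudication matches the definitions", {
  prods <- mini_products(c("shark", "flake", "flake", "flake"))
  calls <- mini_calls(c("Carcharhinus plumbeus",   # a shark under 'shark'
                        "Callorhinchus milii",     # holocephalan
                        "Galeorhinus galeus",      # school shark
                        "Mustelus antarcticus"))   # gummy shark
  adj <- adjudicate_products(prods, calls, ref)
  expect_equal(adj$status_comprehensive,
               c("correct", "mislabelled", "correct", "correct"))
  expect_equal(adj$status_lenient_flake,
               c("correct", "correct", "correct", "correct"))
  expect_equal(adj$status_strict_flake,
               c("correct", "mislabelled", "mislabelled", "correct"))
})

test_that("synonym drift does not create false mislabelling", {
  prods <- mini_products("king prawn", groups = "prawns")
  calls <- mini_calls("Melicertus plebejus")  # database synonym
  adj <- adjudicate_products(prods, calls, ref)
  expect_equal(adj$assigned_species, "Penaeus plebejus")
  expect_equal(adj$status_comprehensive, "correct")
})

test_that("universal generics and unknown terms are handled explicitly", {
  prods <- mini_products(c("fish", "mystery thing", "flake"))
  calls <- mini_calls(c("Lates calcarifer", "Lates calcarifer", NA))
  adj <- adjudicate_products(prods, calls, ref)
  expect_equal(adj$status_comprehensive,
               c("correct", "unassessable", "unassessable"))
  expect_true(adj$unknown_term[2])
  expect_false(adj$unknown_term[1])
})

test_that("rates exclude the unassessable and keep denominators honest", {
  prods <- mini_products(rep("flake", 10))
  sp <- c(rep("Callorhinchus milii", 3), rep("Mustelus antarcticus", 4),
          rep(NA, 3))
  adj <- adjudicate_products(prods, mini_calls(sp), ref)
  r <- mislabelling_rates(adj, prods)
  expect_equal(r$numerator, 3)
  expect_equal(r$denominator, 7)
  expect_equal(r$proportion, 300 / 7)
  # assessed + unassessable = total, for every stratification
  for (by in c("overall", "group", "origin", "outlet", "specificity")) {
    tab <- mislabelling_rates(adj, prods, by = by)
    expect_equal(sum(tab$denominator),
                 sum(adj$status_comprehensive != "unassessable"))
  }
})

test_that("zero mislabelling yields a truncated interval at zero", {
  prods <- mini_products(rep("flake", 5))
  adj <- adjudicate_products(prods,
                             mini_calls(rep("Mustelus antarcticus", 5)), ref)
  r <- mislabelling_rates(adj, prods)
  expect_equal(r$proportion, 0)
  expect_equal(r$ci_low, 0)
})

test_that("a 20 percent cohort is recovered within three standard errors", {
  set.seed(31)
  d <- study_design(seed = 31, samples_per_state = 143,
                    true_mislabel_prob = prob_matrix(rep(0.2, 4)))
  gen <- generate_products(d, ref)
  adj <- adjudicate_products(gen$products, truth_calls(gen$truth), ref)
  r <- mislabelling_rates(adj, gen$products)
  se <- 100 * sqrt(0.2 * 0.8 / r$denominator)
  expect_lt(abs(r$proportion - 20), 3 * se)
})

test_that("the sensitivity table only moves cells the regime touches", {
  d <- study_design(seed = 5)
  gen <- generate_products(d, ref)
  adj <- adjudicate_products(gen$products, truth_calls(gen$truth), ref)
  tab <- sensitivity_analysis(adj, gen$products)
  comp <- tab[tab$regime == "comprehensive", ]
  strict <- tab[tab$regime == "strict_flake", ]
  for (g in c("hoki", "prawns", "snapper", "squid_cuttlefish", "tuna"))
    expect_equal(strict$proportion[strict$stratum == g],
                 comp$proportion[comp$stratum == g])
  expect_gte(strict$proportion[strict$stratum == "sharks_rays"],
             comp$proportion[comp$stratum == "sharks_rays"])
})

test_that("sensitivity analysis refuses mismatched sample coverage", {
  prods <- mini_products(c("flake", "flake"))
  adj <- adjudicate_products(prods,
                             mini_calls(rep("Mustelus antarcticus", 2)), ref)
  adj$status_strict_flake[1] <- "unassessable"
  expect_error(sensitivity_analysis(adj, prods), "coverage")
})

test_that("Goodman intervals match the closed form and its symmetries", {
  one <- goodman_intervals(c(x = 10))
  expect_equal(one$proportion, 100)
  expect_gte(one$ci_high, 100 - 1e-9)

  four <- goodman_intervals(c(25, 25, 25, 25))
  expect_equal(length(unique(round(four$ci_low, 9))), 1)
  expect_true(all(four$ci_low < 25 & four$ci_high > 25))
  # hand-computed from the quadratic at alpha = 0.05, k = 4, N = 100
  A <- qchisq(1 - 0.05 / 4, 1)
  lo <- (A + 50 - sqrt(A * (A + 4 * 25 * 75 / 100))) / (2 * (100 + A))
  expect_equal(four$ci_low[1], 100 * lo)

  # same count and total, more categories: the Bonferroni quantile grows,
  # so the interval for a count of 25 out of 100 widens from k = 2 to 4
  k2 <- goodman_intervals(c(25, 75))
  expect_lt(four$ci_low[1], k2$ci_low[1])
  expect_gt(four$ci_high[1], k2$ci_high[1])
  expect_error(goodman_intervals(c(0, 0)), "positive")
})

test_that("vendor claims are compared but never change the adjudication", {
  prods <- mini_products(c("flake", "flake", "flake"))
  prods$vendor_claim <- c("Mustelus antarcticus",   # agrees
                          "Callorhinchus milii",    # rescue candidate
                          NA)
  calls <- mini_calls(c("Mustelus antarcticus", "Callorhinchus milii",
                        "Mustelus lenticulatus"))
  adj <- adjudicate_products(prods, calls, ref)
  vc <- vendor_comparison(adj, prods, ref)
  expect_equal(vc$n_claims, 2)
  expect_equal(vc$agree, 2)
  expect_equal(vc$rescued, 1)
  expect_equal(vc$absent, 1)
  # the written-label adjudication is untouched
  expect_equal(adj$status_comprehensive[2], "mislabelled")
})

test_that("conservation annotation is a key-exact, order-free join", {
  prods <- mini_products(c("flake", "flake"))
  calls <- mini_calls(c("Galeorhinus galeus", "Mustelus antarcticus"))
  adj <- adjudicate_products(prods, calls, ref)
  tab <- data.frame(species = c("Galeorhinus galeus", "Sphyrna zygaena"),
                    category = c("Critically Endangered", "Vulnerable"),
                    stringsAsFactors = FALSE)
  a1 <- annotate_conservation(adj, tab, ref)
  a2 <- annotate_conservation(adj, tab[2:1, ], ref)
  expect_equal(a1$conservation, c("Critically Endangered", "unknown"))
  expect_identical(a1$conservation, a2$conservation)
  a3 <- annotate_conservation(adj, tab[0, ], ref)
  expect_equal(a3$conservation, c("unknown", "unknown"))
})
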