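# Bioassay arithmetic and structure-activity pair contrasts.

test_that("percent inhibition follows its definition and guards", {
  expect_equal(percent_inhibition(2, 2), 0)
  expect_equal(percent_inhibition(2, 0), 100)
  expect_equal(percent_inhibition(2.0, 1.5), 25)
  expect_error(percent_inhibition(0, 1), "positive")
  expect_error(percent_inhibition(2, -1), "non-negative")
})

test_that("relative potency is a scale-invariant ratio", {
  expect_equal(relative_potency(40, 40), 100)
  expect_equal(relative_potency(0, 40), 0)
  expect_equal(relative_potency(40, 32), 125)
  expect_error(relative_potency(10, 0), "positive")
  set.seed(1)
  for (k in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); s <- runif(1, 0.1, 10)
    expect_equal(relative_potency(s * a, s * b), relative_potency(a, b),
                 tolerance = 1e-12)
  }
})

test_that("selectivity index is a reciprocal-antisymmetric ratio", {
  expect_equal(selectivity_index(1, 1), 1)
  expect_equal(selectivity_index(23.096, 1), 23.096)
  expect_error(selectivity_index(-1, 2), "positive")
  set.seed(2)
  for (k in 1:20) {
    a <- runif(1, 0.01, 50); b <- runif(1, 0.01, 50)
    expect_equal(selectivity_index(a, b), a / b, tolerance = 1e-12)
    expect_equal(selectivity_index(a, b) * selectivity_index(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("the packaged bioactivity table is well-formed", {
  tab <- bioactivity_table()
  expect_true(all(tab$value[tab$endpoint == "cox1_ic50"] > 0))
  expect_true(all(is.finite(tab$value)))
  # exactly one reference drug per endpoint
  refs <- tapply(tab$is_reference, tab$endpoint, sum)
  expect_true(all(refs == 1))
  # no duplicated compound within an endpoint
  expect_false(any(duplicated(tab[c("id", "endpoint")])))
})

test_that("pair contrasts report signed differences and verdicts", {
  tab <- bioactivity_table()
  pairs <- data.frame(id_a = "5a", id_b = "5b",
                      endpoint = "anti_inflammatory_potency",
                      label = "ortho vs para")
  rep1 <- sar_pair_report(tab, pairs)
  expect_equal(rep1$difference, 117.6 - 116.5, tolerance = 1e-12)
  expect_equal(rep1$verdict, "a > b")
  # swapped pair negates the difference
  rep2 <- sar_pair_report(tab, data.frame(
    id_a = "5b", id_b = "5a", endpoint = "anti_inflammatory_potency"))
  expect_equal(rep2$difference, -rep1$difference)
  expect_equal(rep2$verdict, "b > a")
  # equal values tie
  tie_tab <- data.frame(id = c("x", "y"), endpoint = "e", value = c(1, 1),
                        is_reference = c(TRUE, FALSE))
  tie <- sar_pair_report(tie_tab, data.frame(id_a = "x", id_b = "y",
                                             endpoint = "e"))
  expect_equal(tie$verdict, "tie")
  expect_equal(tie$difference, 0)
  # unprinted cells raise an error naming the compound
  expect_error(sar_pair_report(tab, data.frame(
    id_a = "5f", id_b = "5e", endpoint = "anti_inflammatory_potency")),
    "5f")
})

test_that("printed values reproduce the ortho/para and halogen orderings", {
  tab <- bioactivity_table()
  pairs <- data.frame(
    id_a = c("5a", "5e", "8a", "8e", "5b", "5b", "5f", "8f"),
    id_b = c("5b", "5f", "8b", "8f", "5c", "5a", "5e", "8b"),
    endpoint = c("anti_inflammatory_potency", "central_analgesic_potency",
                 "peripheral_analgesic_potency",
                 "peripheral_analgesic_potency",
                 "peripheral_analgesic_potency",
                 "peripheral_analgesic_potency",
                 "peripheral_analgesic_potency",
                 "central_analgesic_potency"),
    label = c("ortho > para (anti-inflammatory)",
              "ortho > para (central)",
              "ortho > para (peripheral, indomethacin series)",
              "ortho > para (peripheral, indomethacin series)",
              "chloro > fluoro (peripheral)",
              "para > ortho (peripheral, ibuprofen series)",
              "para > ortho (peripheral, ibuprofen series)",
              "methoxy > chloro (central, indomethacin series)"))
  rep <- sar_pair_report(tab, pairs)
  expect_true(all(rep$verdict == "a > b"))
})
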