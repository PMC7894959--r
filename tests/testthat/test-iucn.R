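paper_facts <- assessment_input(
  eoo_km2 = 28.7, aoo_km2 = 8, n_locations = 5,
  severely_fragmented = TRUE,
  continuing_decline = c("i", "ii", "iii", "v"),
  extreme_fluctuations = c("i", "ii", "iv"),
  n_mature = 130)

test_that("restricted-range facts yield CR with the full criterion codes", {
  b <- assess_criterion_b(paper_facts)
  expect_equal(b$B1$category, "CR")
  expect_equal(b$B2$category, "CR")
  expect_equal(b$B1$code, "B1ab(i,ii,iii,v)c(i,ii,iv)")
  expect_equal(b$B2$code, "B2ab(i,ii,iii,v)c(i,ii,iv)")
  res <- assess(paper_facts)
  expect_equal(res$category, "CR")
  expect_true(all(c("B1ab(i,ii,iii,v)c(i,ii,iv)",
                    "B2ab(i,ii,iii,v)c(i,ii,iv)") %in% res$codes))
})

test_that("area thresholds are strict and B1/B2 are independent", {
  at_boundary <- assessment_input(
    eoo_km2 = 100, aoo_km2 = 8, n_locations = 5,
    severely_fragmented = TRUE,
    continuing_decline = c("i", "ii", "iii", "v"),
    extreme_fluctuations = c("i", "ii", "iv"))
  b <- assess_criterion_b(at_boundary)
  expect_equal(b$B1$category, "EN")   # 100 is not < 100
  expect_equal(b$B2$category, "CR")   # AOO still < 10

  wide <- assessment_input(eoo_km2 = 50000, aoo_km2 = 5000)
  bw <- assess_criterion_b(wide)
  expect_true(is.na(bw$B1$category))
  expect_true(is.na(bw$B2$category))
})

test_that("criterion B needs two of the three conditions", {
  # drop the decline flags: fragmentation + fluctuations still qualify
  no_decline <- assessment_input(
    eoo_km2 = 28.7, aoo_km2 = 8, severely_fragmented = TRUE,
    extreme_fluctuations = c("i", "ii", "iv"))
  expect_equal(assess_criterion_b(no_decline)$category, "CR")
  # drop fluctuations too: only one condition left, B no longer triggers
  only_frag <- assessment_input(eoo_km2 = 28.7, aoo_km2 = 8,
                                severely_fragmented = TRUE)
  bb <- assess_criterion_b(only_frag)
  expect_true(is.na(bb$B1$category))
  expect_true(is.na(bb$B2$category))
})

test_that("population-size and quantitative-risk criteria apply their
           thresholds", {
  expect_equal(assess_criterion_d(130), "EN")
  expect_equal(assess_criterion_d(49), "CR")
  expect_true(is.na(assess_criterion_d(1e6)))

  expect_equal(assess_criterion_e(0.478, 50), "VU")
  expect_equal(assess_criterion_e(0.5, 10), "CR")
  expect_true(is.na(assess_criterion_e(0.05, 100)))
})

test_that("the overall category is the most severe and LC is the floor", {
  res <- assess(paper_facts)
  expect_equal(res$criteria$D, "EN")
  expect_equal(res$category, "CR")

  benign <- assessment_input(eoo_km2 = 1e6, aoo_km2 = 1e5, n_mature = 1e6)
  expect_equal(assess(benign)$category, "LC")

  nothing <- assessment_input()
  expect_error(assess(nothing), class = "endemica_validation_error")
})

test_that("criterion codes round-trip through the parser", {
  b <- assess_criterion_b(paper_facts)
  for (code in c(b$B1$code, b$B2$code)) {
    parsed <- parse_b_code(code)
    expect_true(parsed$cond_a)
    expect_equal(parsed$decline, c("i", "ii", "iii", "v"))
    expect_equal(parsed$fluctuation, c("i", "ii", "iv"))
  }
  p2 <- parse_b_code("B2b(iii)")
  expect_false(p2$cond_a)
  expect_equal(p2$decline, "iii")
  expect_equal(p2$fluctuation, character(0))
})

test_that("worsening any single input never improves the category", {
  set.seed(1234)
  sev <- function(cat) match(cat, c("LC", "NT", "VU", "EN", "CR"))
  rand_input <- function() {
    assessment_input(
      eoo_km2 = runif(1, 1, 40000),
      aoo_km2 = runif(1, 0.5, 4000),
      n_locations = sample(1:20, 1),
      severely_fragmented = runif(1) < 0.5,
      continuing_decline = sample(c("i", "ii", "iii", "iv", "v"),
                                  sample(0:5, 1)),
      extreme_fluctuations = sample(c("i", "ii", "iii", "iv"),
                                    sample(0:4, 1)),
      n_mature = sample(c(10, 40, 100, 240, 900, 1050, 5000), 1))
  }
  worsen <- function(inp) {
    choice <- sample(6, 1)
    if (choice == 1) inp$eoo_km2 <- inp$eoo_km2 * runif(1, 0.05, 0.95)
    if (choice == 2) inp$aoo_km2 <- inp$aoo_km2 * runif(1, 0.05, 0.95)
    if (choice == 3) inp$n_locations <- max(1, inp$n_locations -
                                              sample(1:5, 1))
    if (choice == 4) inp$severely_fragmented <- TRUE
    if (choice == 5) {
      inp$continuing_decline <- sort(unique(c(inp$continuing_decline,
                                              sample(1:5, 1))))
      inp$extreme_fluctuations <- sort(unique(c(inp$extreme_fluctuations,
                                                sample(1:4, 1))))
    }
    if (choice == 6) inp$n_mature <- floor(inp$n_mature * runif(1, 0.1, 0.9))
    inp
  }
  for (i in 1:1000) {
    a <- rand_input()
    b <- worsen(a)
    expect_gte(sev(assess(b)$category), sev(assess(a)$category))
  }
})

test_that("the fluctuation helper applies the order-of-magnitude rule", {
  expect_false(flag_extreme_fluctuation(c(130, 109, 68, 79, 110))$extreme)
  expect_equal(flag_extreme_fluctuation(c(130, 68))$ratio, 130 / 68,
               tolerance = 1e-12)
  expect_true(flag_extreme_fluctuation(c(10, 120))$extreme)
  expect_true(flag_extreme_fluctuation(c(0, 50))$extreme)
})
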