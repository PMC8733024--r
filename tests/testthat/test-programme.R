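test_that("phenotyping respects the heritability contract", {
  f <- mini_founders()
  tr <- assign_trait(f$panel, f$map, 0.1, seed = 7L)
  # h2 = 1: phenotype equals the genetic value exactly
  ph1 <- phenotype_cohort(f$panel, tr, h2 = 1, year = 1L, stage = "X",
                          seed = 1L)
  expect_equal(ph1$value, unname(true_genetic_values(f$panel, tr)))
  expect_error(phenotype_cohort(f$panel, tr, h2 = 0, 1L, "X"), "h2")
  expect_error(phenotype_cohort(f$panel, tr, h2 = 1.2, 1L, "X"), "h2")
})

test_that("squared phenotype-genetic correlation matches h2 on a large DH cohort", {
  f <- mini_founders()
  tr <- assign_trait(f$panel, f$map, 0.1, seed = 7L)
  cr <- make_crosses(f$panel, f$map, n_crosses = 50L, n_f1_per_cross = 100L,
                     seed = 8L)
  dh <- double_haploids(cr$panel, f$map, seed = 9L)
  ph <- phenotype_cohort(dh, tr, h2 = 0.1, year = 1L, stage = "HDRW",
                         seed = 10L)
  g <- true_genetic_values(dh, tr)
  # realised h2 = Vg / (Vg + 0.9); the cohort's Vg need not be exactly 0.1
  expected <- var_1n(g) / (var_1n(g) + 0.9)
  expect_equal(cor(ph$value, unname(g))^2, expected, tolerance = 0.25)
})

test_that("truncation selection ranks by mean phenotype with id tie-break", {
  ph <- tibble::tibble(id = c("a", "b", "c"), value = c(3, 1, 2))
  expect_equal(select_top(ph, 2L), c("a", "c"))
  expect_equal(sort(select_top(ph, 3L)), c("a", "b", "c"))
  expect_error(select_top(ph, 4L), "cannot select")
  # repeated records average; ties break on id
  ph2 <- tibble::tibble(id = c("b", "b", "a"), value = c(1, 3, 2))
  expect_equal(select_top(ph2, 1L), "a")
})

test_that("the miniature programme has the expected pipeline structure", {
  sim <- mini_sim()
  p <- sim$params
  counts <- dplyr::count(sim$cohorts, .data$year, .data$stage)
  full_years <- 8:10 # pipeline fully primed
  for (y in full_years) {
    get_n <- function(st) counts$n[counts$year == y & counts$stage == st]
    expect_equal(get_n("F1"), p$n_crosses * p$n_f1_per_cross)
    expect_equal(get_n("HDRW"), p$n_crosses * p$n_f1_per_cross)
    expect_equal(get_n("PYT"), p$n_pyt)
    expect_equal(get_n("AYT"), p$n_ayt)
    expect_equal(get_n("EYT1"), p$n_eyt)
    expect_equal(get_n("EYT2"), p$n_eyt)
  }
  # one variety per completed cycle
  expect_equal(nrow(sim$varieties), sum(seq_len(p$years) + 6L <= p$years))
  # every DH line has two recorded parents
  expect_true(all(!is.na(sim$pedigree$p1) & !is.na(sim$pedigree$p2)))
  # training extract counts follow from the window arithmetic
  w <- length(p$training_years)
  expect_equal(nrow(sim$training$phenotypes),
               w * p$n_pyt + w * p$n_ayt + (w - 1L + w - 2L) * p$n_eyt)
  # distinct lines: every PYT entrant of the window is new; the first window
  # year adds its AYT cohort (from the pre-window PYT); EYT cohorts add new
  # lines only when their source crops predate the window, which needs the
  # window to start in year >= 8 -- here it starts in year 5
  expect_equal(nrow(sim$training$genotypes), w * p$n_pyt + p$n_ayt)
})

test_that("recorded true partitions satisfy the decomposition identity", {
  sim <- mini_sim()
  wide <- true_components(sim) |>
    tidyr::pivot_wider(names_from = "component", values_from = "value")
  gap <- wide$total - wide$genic - wide$within_ld - wide$between_ld
  expect_true(all(abs(gap) <= 1e-8 * pmax(1, abs(wide$total))))
  # per-cohort variances re-derivable from the recorded true values
  tv <- sim$true_values
  hd <- tv[tv$stage == "HDRW" & tv$year == 7L, ]
  expect_equal(var_1n(hd$g),
               wide$total[wide$stage == "HDRW" & wide$year == 7L])
})

test_that("runs are reproducible and seeds matter", {
  p <- mini_params(years = 8L)
  a <- run_programme(p, seed = 11L)
  b <- run_programme(p, seed = 11L)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$training$genotypes, b$training$genotypes)
  c <- run_programme(p, seed = 12L)
  expect_false(identical(a$phenotypes$value, c$phenotypes$value))
})

test_that("genotype-by-year deviations calibrate and decorrelate years", {
  f <- mini_founders()
  tr <- assign_trait(f$panel, f$map, 0.1, seed = 7L)
  # zero interaction variance leaves the trait untouched
  expect_identical(add_gxy_deviations(tr, 1:5, 0, f$panel, seed = 1L), tr)
  tr_g <- add_gxy_deviations(tr, 1:400, 0.2, f$panel, seed = 1L)
  Q <- panel_dosages(f$panel, tr$qtl)
  dev_var <- apply(tr_g$gxy, 2L, function(d) var_1n(drop(Q %*% d)))
  expect_equal(mean(dev_var), 0.2, tolerance = 0.1)
  # year-specific genetic values are imperfectly correlated across years
  g1 <- true_genetic_values(f$panel, tr_g, year = 1L)
  g2 <- true_genetic_values(f$panel, tr_g, year = 2L)
  expect_lt(cor(g1, g2), 1)
  expect_gt(cor(g1, g2), 0) # base effects still dominate
})

test_that("selection depletes genetic relative to genic variance (Bulmer)", {
  # small replicates: late-stage selected cohorts show negative LD so total
  # genetic variance drops below genic variance in the large majority
  hits <- 0L; n_rep <- 10L
  for (s in seq_len(n_rep)) {
    sim <- run_programme(mini_params(years = 9L), seed = 100L + s)
    wide <- true_components(sim) |>
      tidyr::pivot_wider(names_from = "component", values_from = "value")
    eyt <- wide[wide$stage == "EYT" & wide$year == 9L, ]
    hits <- hits + as.integer(eyt$total < eyt$genic)
  }
  expect_gte(hits, 8L)
})

test_that("without selection the between-chromosome LD contribution averages to zero", {
  vals <- vapply(1:8, function(s) {
    sim <- run_programme(mini_params(years = 9L, selection = "random"),
                         seed = 200L + s)
    wide <- true_components(sim) |>
      tidyr::pivot_wider(names_from = "component", values_from = "value")
    late <- wide[wide$year >= 7L & wide$stage %in% c("PYT", "AYT", "EYT"), ]
    mean(late$between_ld / late$total)
  }, numeric(1))
  # drift alone is not coupled to effects: mean contribution near zero,
  # and far smaller than under selection
  expect_lt(abs(mean(vals)), 0.12)
})
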