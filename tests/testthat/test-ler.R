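ler_row <- function(gen, crop, ic, sole, season = "1", system = "IC1") {
  data.frame(genotype = gen, season = season, system = system, crop = crop,
             intercrop_mean = ic, sole_mean = sole)
}

test_that("LER arithmetic, favorability threshold, and limits", {
  # substitutive limit: each component at half its sole yield -> LER = 1
  inp <- rbind(ler_row("H1", "maize", 2.5, 5), ler_row("H1", "soy", 1, 2))
  lt <- ler(inp)
  expect_equal(lt$LER, 1)
  expect_false(lt$favorable)  # strictly greater than 1 is favorable

  # 3/5 + 1/2 = 1.1, favorable
  lt2 <- ler(rbind(ler_row("H1", "maize", 3, 5), ler_row("H1", "soy", 1, 2)))
  expect_equal(lt2$LER, 1.1)
  expect_true(lt2$favorable)

  # each component equal to sole -> LER = number of components
  lt3 <- ler(rbind(ler_row("H1", "maize", 5, 5), ler_row("H1", "soy", 2, 2),
                   ler_row("H1", "potato", 3, 3)))
  expect_equal(lt3$LER, 3)
  expect_equal(lt3$n_crops, 3L)
})

test_that("LER is scale-invariant and strictly monotone in intercrop yield", {
  base <- rbind(ler_row("H1", "maize", 3.2, 5.1), ler_row("H1", "soy", 0.8, 2.3))
  l0 <- ler(base)$LER
  scaled <- base
  scaled$intercrop_mean <- scaled$intercrop_mean * 7.3
  scaled$sole_mean <- scaled$sole_mean * 7.3
  expect_equal(ler(scaled)$LER, l0, tolerance = 1e-12)

  up <- base; up$intercrop_mean[1] <- up$intercrop_mean[1] + 0.01
  expect_gt(ler(up)$LER, l0)
})

test_that("domain errors: zero sole yield names the crop, missing data caught", {
  bad <- rbind(ler_row("H1", "maize", 3, 5), ler_row("H1", "soy", 1, 0))
  expect_error(ler(bad), "division-domain.*soy")
  bad2 <- ler_row("H1", "maize", NA, 5)
  expect_error(ler(bad2), "incomplete")
  expect_error(ler(data.frame(genotype = "H1")), "missing column")
})

test_that("favorability counts per stratum, including the all-unfavorable case", {
  df <- data.frame(genotype = paste0("G", 1:4), season = "1", system = "IC1",
                   LER = c(0.5, 0.5, 0.5, 0.5))
  lt <- ler_table(df)
  expect_equal(favorability_count(lt, "1", "IC1"), 0L)
  expect_error(favorability_count(lt, "2", "IC1"), "lookup error")
})

test_that("published LER table reproduces the reported favorability counts", {
  ml <- ler_table(read.csv(system.file("extdata", "maize_ler.csv",
                                       package = "metstab")))
  expect_equal(nrow(ml), 24 * 8)
  # grain yield, maize+sweet potato, season 2: seven favorable genotypes
  expect_equal(favorability_count(ml, 2, "IC2", "GY"), 7L)
  sel <- ml$trait == "GY" & ml$system == "IC2" & ml$season == 2 & ml$favorable
  expect_setequal(ml$genotype[sel],
                  c("T4", "H18", "H10", "H9", "T2", "H3", "H12"))
  # biomass, maize+soybean, season 2: all favorable except H15 and H16
  expect_equal(favorability_count(ml, 2, "IC1", "CWH"), 22L)
  unf <- ml$trait == "CWH" & ml$system == "IC1" & ml$season == 2 & !ml$favorable
  expect_setequal(ml$genotype[unf], c("H15", "H16"))
  # biomass, maize+soybean, season 1: every genotype favorable
  expect_equal(favorability_count(ml, 1, "IC1", "CWH"), 24L)
})

test_that("maize-side partial LER input comes from matched cell means", {
  tab <- simulate_study(seed = 5)
  lin <- partial_ler_input(tab, "GY", sole_system = "sole")
  expect_setequal(unique(lin$system), c("soybean", "sweetpotato"))
  expect_equal(nrow(lin), 24 * 2 * 2)
  # hand-check one row
  r <- lin[lin$genotype == "G01" & lin$season == "S1" &
             lin$system == "soybean", ]
  ic <- mean(tab$GY[tab$genotype == "G01" & tab$season == "S1" &
                      tab$system == "soybean"])
  so <- mean(tab$GY[tab$genotype == "G01" & tab$season == "S1" &
                      tab$system == "sole"])
  expect_equal(r$intercrop_mean, ic)
  expect_equal(r$sole_mean, so)
  # maize-only partial LER flows through ler()
  lt <- ler(lin)
  expect_equal(nrow(lt), 24 * 2 * 2)
  expect_equal(lt$LER[lt$genotype == "G01" & lt$season == "S1" &
                        lt$system == "soybean"], ic / so)
  # ranking column: descending with min ties inside each stratum
  lr <- ler_ranks(lt)
  one <- lr[lr$season == "S1" & lr$system == "soybean", ]
  expect_equal(one$rank, rank_values(one$LER, "descending"))
})
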