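test_that("eye area equals the spherical-shell formula and its simplification", {
  # hemisphere: all three chords equal L gives 2*pi*L^2
  expect_equal(eye_area(100, 100, 100), 2 * pi * 100^2)
  # long form as displayed vs the simplified pi*(L^2 + W^2) implementation
  set.seed(1)
  W <- runif(1e3, 10, 5000)
  H <- runif(1e3, 10, 5000)
  Lw <- runif(1e3, 10, 5000)
  long_form <- 2 * pi * W * ((((H + Lw) / 2)^2 + W^2) / (2 * W))
  expect_equal(eye_area(W, H, Lw), long_form, tolerance = 1e-12)
  expect_error(eye_area(-1, 10, 10), "positive")
})

test_that("ommatidium area uses the printed hexagon constant", {
  expect_equal(ommatidium_area(2), 2.598)    # radius 1
  # printed constant vs exact hexagon area 3*sqrt(3)/2 * r^2
  r <- c(0.5, 1, 7.3, 12)
  exact <- 3 * sqrt(3) / 2 * r^2
  rel <- abs(ommatidium_area(2 * r) - exact) / exact
  expect_true(all(rel < 3.2e-5) && all(rel > 2.8e-5))
  expect_error(ommatidium_area(0), "positive")
})

test_that("ommatidium count is the area ratio, unrounded", {
  # species-mean chords give a count within 1% of the published species
  # mean (which averages per-specimen ratios, hence the Jensen gap)
  n <- ommatidia_number(887826.7, 341.2)
  expect_equal(n, 2602.07, tolerance = 1e-4)
  expect_lt(abs(n - 2585.2) / 2585.2, 0.01)
  expect_equal(ommatidia_number(123.4, 123.4), 1)
  expect_error(ommatidia_number(100, 0), "positive")
})

test_that("interommatidial angle back-calculates the published species values", {
  expect_lt(abs(interommatidial_angle(2635.3) - 3.01), 0.05)
  expect_lt(abs(interommatidial_angle(1123.8) - 4.63), 0.05)
  # all 18 species rows: the deg^2 constant reproduces the printed angles
  t1 <- builtin_fixture("table1")
  om <- trait_means(t1, "OM_number")
  dg <- trait_means(t1, "delta_gamma", species = names(om))
  err <- abs(interommatidial_angle(om) - dg)
  expect_lt(median(err), 0.06)
  # the small-scale printed constant would give radian-scale nonsense
  expect_lt(interommatidial_angle(2635.3, constant = 23.818), 0.2)
})

test_that("interommatidial angle is monotone with the sqrt scaling", {
  om <- seq(500, 5000, by = 250)
  ang <- interommatidial_angle(om)
  expect_true(all(diff(ang) < 0))
  expect_equal(interommatidial_angle(2 * om), ang / sqrt(2))
})

test_that("body mass follows the brachyceran allometry", {
  expect_equal(body_mass(1), 0.655)
  expect_equal(body_mass(2), 0.655 * 2^2.526)
  expect_equal(body_mass(2000, unit = "um"), body_mass(2))
  expect_error(body_mass(0), "positive")
})

test_that("relative traits are linear in the trait and scale-free", {
  expect_equal(relative_trait(2135, 2135), 100)
  expect_equal(relative_trait(2 * 471.3, 2049), 2 * relative_trait(471.3, 2049))
  # funiculus/head ratio of a typical non-satellite species
  expect_equal(relative_trait(471.3, 2049.0), 23.0, tolerance = 1e-3)
  expect_error(relative_trait(100, 0), "positive")
})

make_specimens <- function(n_per = 5, cv = 0.03, seed = 99) {
  set.seed(seed)
  base <- list(
    sp1 = c(H = 2300, W = 1000, Hh = 1100, Lw = 1050, om = 20, oc = 55,
            f = 300, p = 230, a = 540),
    sp2 = c(H = 1500, W = 700, Hh = 760, Lw = 730, om = 18, oc = 54,
            f = 460, p = 170, a = 180)
  )
  rows <- lapply(names(base), function(sp) {
    b <- base[[sp]]
    data.frame(
      species_id = sp,
      specimen_id = paste0(sp, "_", seq_len(n_per)),
      H_width = b["H"] * rlnorm(n_per, 0, cv),
      E_widthA = b["W"] * rlnorm(n_per, 0, cv),
      E_height = b["Hh"] * rlnorm(n_per, 0, cv),
      E_widthL = b["Lw"] * rlnorm(n_per, 0, cv),
      OM_diameter_1 = b["om"] * rlnorm(n_per, 0, cv),
      OM_diameter_2 = b["om"] * rlnorm(n_per, 0, cv),
      OC_diameter = b["oc"] * rlnorm(n_per, 0, cv),
      F_length = b["f"] * rlnorm(n_per, 0, cv),
      P_length = b["p"] * rlnorm(n_per, 0, cv),
      A_length = b["a"] * rlnorm(n_per, 0, cv)
    )
  })
  specimen_measurements(do.call(rbind, rows))
}

test_that("species aggregation derives per specimen, then averages", {
  specs <- make_specimens()
  derived <- derive_specimen_traits(specs)
  # count identity holds per specimen to machine precision
  expect_equal(derived$E_area / derived$OM_area, derived$OM_number,
               tolerance = 1e-14)
  tab <- aggregate_species(specs)
  expect_s3_class(tab, "species_traits")
  expect_setequal(unique(tab$species_id), c("sp1", "sp2"))
  expect_true(all(c("E_area", "OM_number", "delta_gamma", "ANT_length")
                  %in% tab$trait))
  expect_true(all(tab$n == 5))
  # two identical specimens: mean is the value, SE collapses to 0
  two <- make_specimens(n_per = 1, cv = 0)
  two2 <- rbind(two, two)
  two2$specimen_id <- paste0(two2$specimen_id, rep(c("", "_b"), each = 2))
  tab2 <- aggregate_species(specimen_measurements(two2))
  expect_equal(unique(tab2$se), 0)
  # a single specimen reports the honest missing SE, n = 1
  tab1 <- aggregate_species(make_specimens(n_per = 1))
  expect_true(all(is.na(tab1$se)) && all(tab1$n == 1))
})

test_that("the Jensen gap between aggregation orders vanishes with noise", {
  gap_for <- function(cv) {
    specs <- make_specimens(n_per = 40, cv = cv, seed = 11)
    tab <- aggregate_species(specs)
    sp1 <- tab[tab$species_id == "sp1", ]
    mean_of_ratios <- sp1$mean[sp1$trait == "OM_number"]
    ratio_of_means <- sp1$mean[sp1$trait == "E_area"] /
      sp1$mean[sp1$trait == "OM_area"]
    abs(mean_of_ratios - ratio_of_means) / ratio_of_means
  }
  g_small <- gap_for(0.001)
  g_large <- gap_for(0.15)
  expect_lt(g_small, 1e-5)
  expect_gt(g_large, g_small)
  # gap is bounded by the order of the squared coefficient of variation
  expect_lt(g_large, 10 * 0.15^2)
})

test_that("aggregation recovers known species values from noisy specimens", {
  specs <- make_specimens(n_per = 30, cv = 0.03, seed = 3)
  tab <- aggregate_species(specs)
  sp1 <- tab[tab$species_id == "sp1", ]
  # truth computed from the noiseless base values
  E_true <- eye_area(1000, 1100, 1050)
  OM_true <- ommatidium_area(20)
  for (pair in list(c("H_width", 2300), c("OC_diameter", 55),
                    c("E_area", E_true), c("OM_area", OM_true))) {
    row <- sp1[sp1$trait == pair[1], ]
    expect_lt(abs(row$mean - as.numeric(pair[2])),
              4 * row$se + 0.01 * as.numeric(pair[2]))
  }
})
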