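test_that("parameter-to-radius conversion matches the limit anchors and known cases", {
  rules12 <- sedem_rules("classic12")
  # derived densimetric indices and their radii for the reference excipient
  da <- 0.38; dc <- 0.71
  ie <- interparticle_porosity(da, dc)
  expect_equal(ie, 1.223, tolerance = 5e-4)
  vals <- c(Da = da, Dc = dc, Ie = ie, IC = carr_index(da, dc), Icd = 34.2,
            IH = hausner_ratio(da, dc), theta = 19.8, t_flow = 8.1,
            HR = 2.77, H = 0.2, Pf = 9.1, Itheta = 0.0154)
  pp <- powder_parameter_set("ludipress", vals, "classic12")
  expect_warning(prof <- convert_parameters(pp), "outside the SeDeM limit range")
  expect_equal(round_half_up(prof$radii[["Ie"]], 2), 10.19)  # uncapped radius > 10
  expect_equal(round_half_up(prof$radii[["IC"]], 2), 9.30)
  expect_equal(round_half_up(prof$radii[["IH"]], 2), 5.66)
  expect_equal(round_half_up(prof$radii[["Da"]], 2), 3.80)

  # limit cases: worst limit -> 0, best limit -> 10
  worst <- c(Da = 0, Dc = 0, Ie = 0, IC = 0, Icd = 0, IH = 3, theta = 50,
             t_flow = 20, HR = 10, H = 20, Pf = 50, Itheta = 0)
  p0 <- convert_parameters(powder_parameter_set("worst", worst, "classic12"))
  expect_equal(unname(p0$radii), rep(0, 12))
  best <- c(Da = 1, Dc = 1, Ie = 1.2, IC = 50, Icd = 200, IH = 1, theta = 0,
            t_flow = 0, HR = 0, H = 0, Pf = 0, Itheta = 0.02)
  p10 <- convert_parameters(powder_parameter_set("best", best, "classic12"))
  expect_equal(unname(p10$radii), rep(10, 12))

  # capping clips radii into [0, 10]
  expect_warning(capped <- convert_parameters(pp, cap = TRUE))
  expect_true(all(capped$radii <= 10))
  expect_equal(capped$radii[["IC"]], prof$radii[["IC"]])

  # errors: missing parameter is named; negative values rejected
  expect_error(powder_parameter_set("x", vals[-3], "classic12"), "Ie")
  bad <- vals; bad["HR"] <- -1
  expect_error(powder_parameter_set("x", bad, "classic12"), "HR")
})

test_that("conversion round-trips through the inverse transform for every rule", {
  for (variant in c("classic12", "odt15")) {
    rules <- sedem_rules(variant)
    set.seed(42)
    for (rep in 1:20) {
      v <- stats::runif(nrow(rules), pmin(rules$lower, rules$upper),
                        pmax(rules$lower, rules$upper))
      names(v) <- rules$parameter
      prof <- convert_parameters(powder_parameter_set("rt", v, variant))
      expect_equal(invert_radii(prof$radii, rules), v, tolerance = 1e-9)
      expect_true(all(prof$radii >= -1e-12 & prof$radii <= 10 + 1e-12))
    }
  }
})

test_that("incidence means reproduce the published incidence factors", {
  refs <- flurbiprofen_sedem()
  for (mat in names(refs)) {
    inc <- incidence_means(refs[[mat]])
    expect_equal(
      stats::setNames(inc$mean_2dp, inc$incidence),
      printed_incidences_classic[mat, ],
      tolerance = 1e-12
    )
  }
  blends <- flurbiprofen_blends()
  for (f in names(blends)) {
    inc <- incidence_means(blends[[f]])
    keep <- inc$incidence != "disgregability"
    expect_equal(
      stats::setNames(inc$mean_2dp[keep], inc$incidence[keep]),
      printed_incidences_blends[f, ],
      tolerance = 1e-12
    )
    # disgregability is the plain mean of its three radii
    dis <- inc$mean[inc$incidence == "disgregability"]
    expect_equal(dis, mean(blends[[f]]$radii[c("effervescence", "DCD", "DSD")]))
  }
  # all radii equal -> every incidence equals that value
  flat <- radius_profile("flat", stats::setNames(rep(6.4, 15),
                                                 sedem_parameter_names("odt15")))
  expect_true(all(incidence_means(flat)$mean == 6.4))
})

test_that("index summary reproduces every published IP, IPP and IGC/IGCB", {
  refs <- flurbiprofen_sedem()
  for (mat in names(refs)) {
    s <- index_summary(refs[[mat]])
    expect_identical(s$index_name, "IGC")
    expect_equal(s$f, 0.952)
    expect_equal(c(ip = s$ip_2dp, ipp = s$ipp_2dp, igc = s$index_2dp),
                 printed_classic[[mat]])
  }
  blends <- flurbiprofen_blends()
  for (i in seq_len(nrow(printed_blends))) {
    s <- index_summary(blends[[printed_blends$run[i]]])
    expect_identical(s$index_name, "IGCB")
    expect_equal(s$f, 0.950)
    expect_equal(s$ip_2dp, printed_blends$ip[i])
    expect_equal(s$ipp_2dp, printed_blends$ipp[i])
    expect_equal(s$index_2dp, printed_blends$igcb[i])
    expect_identical(s$verdict, "A")
  }
})

test_that("index arithmetic obeys its defining identities", {
  pars <- sedem_parameter_names("classic12")
  # forced by f: all radii 10 give IPP 10 and IGC 9.52
  top <- radius_profile("top", stats::setNames(rep(10, 12), pars),
                        variant = "classic12")
  s <- index_summary(top)
  expect_equal(c(s$ip, s$ipp, s$index), c(1, 10, 9.52))

  set.seed(7)
  for (rep in 1:10) {
    radii <- stats::setNames(round(stats::runif(12, 0, 10), 2), pars)
    prof <- radius_profile("p", radii, variant = "classic12")
    s <- index_summary(prof)
    # IP and IPP against one-line oracles; IGC is exactly IPP * f
    expect_equal(s$ip, sum(radii >= 5) / 12)
    expect_equal(s$ipp, mean(radii))
    expect_equal(s$index, s$ipp * s$f)
    expect_true(s$ipp >= min(radii) && s$ipp <= max(radii))
    # IP invariant under permutation of the radii
    perm <- sample(pars)
    sp <- index_summary(radius_profile("p", radii[perm][pars], variant = "classic12"))
    expect_equal(sp$ip, s$ip)
  }
  # a radius of exactly 5 counts as acceptable
  five <- radius_profile("five", stats::setNames(rep(5, 12), pars),
                         variant = "classic12")
  expect_equal(index_summary(five)$ip, 1)
  expect_error(index_summary(top, f = 0), "'f'")
})

test_that("corrective dose follows the mass-balance blending formula and its edge rules", {
  # compressibility incidences of the reference API and excipient: the
  # blending solution reproduces the published 49.1 % ludipress dose
  expect_equal(corrective_dose(re = 7.07, rp = 3.00, target = 5),
               100 * (5 - 3.00) / (7.07 - 3.00))
  expect_equal(round_half_up(corrective_dose(7.07, 3.00), 1), 49.1)
  expect_equal(corrective_dose(re = 10, rp = 0, target = 5), 50)
  expect_equal(corrective_dose(re = 8, rp = 5, target = 5), 0)   # already at target
  expect_error(corrective_dose(re = 3, rp = 4), "exceed")
  expect_error(corrective_dose(re = 4.5, rp = 3, target = 5), "target")

  # the dosed blend really lands on the target radius
  for (rp in c(0, 2, 4.9)) {
    cp <- corrective_dose(8, rp, 5)
    expect_equal((cp * 8 + (100 - cp) * rp) / 100, 5)
  }
  # monotone: a less deficient API needs less excipient; a higher target more
  rp_grid <- seq(0, 4.5, by = 0.5)
  doses <- vapply(rp_grid, function(rp) corrective_dose(8, rp, 5), numeric(1))
  expect_true(all(diff(doses) < 0))
  tg_grid <- seq(4, 7.5, by = 0.5)
  doses_t <- vapply(tg_grid, function(tg) corrective_dose(8, 1, tg), numeric(1))
  expect_true(all(diff(doses_t) > 0))
})

test_that("radar polygon area agrees with the regular-polygon closed form and shoelace", {
  expect_equal(radar_polygon(rep(10, 12))$area, 6 * sin(pi / 6) * 100)
  expect_equal(radar_polygon(rep(10, 15))$area, 7.5 * sin(2 * pi / 15) * 100)
  for (n in 3:20) {
    r0 <- 4.2
    expect_equal(radar_polygon(rep(r0, n))$area,
                 (n / 2) * sin(2 * pi / n) * r0^2, tolerance = 1e-12)
  }
  # triangle-fan oracle on an irregular profile (independent of shoelace)
  f1 <- flurbiprofen_blends()$F1
  r <- unname(f1$radii)
  n <- length(r)
  fan <- sum(0.5 * r * c(r[-1], r[1]) * sin(2 * pi / n))
  expect_equal(radar_polygon(f1)$area, fan, tolerance = 1e-12)
  expect_error(radar_polygon(c(1, 2)), "at least 3")
})
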