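test_that("G6PDH rate law has the right zeros, inhibitions and magnitude", {
  mp <- metabolism_params("control")
  base <- list(G6P = 40e-6, NADP = 2e-6, NADPH = 55e-6)
  expect_equal(g6pdh_rate(modifyList(base, list(G6P = 0)), mp), 0)
  expect_equal(g6pdh_rate(modifyList(base, list(NADP = 0)), mp), 0)
  v0 <- g6pdh_rate(base, mp)
  expect_gt(v0, 0)
  # independent evaluation of the adopted rate law
  g <- mp$g6pdh
  kg <- g$KmG6P * (1 + mp$ATP / g$KiATP + mp$BPG / g$Ki23BPG)
  kn <- g$KmNADP * (1 + base$NADPH / g$KiNADPH)
  v_oracle <- mp$g6pdh_scale * g$Vmax * base$G6P * base$NADP /
    ((kg + base$G6P) * (kn + base$NADP))
  expect_equal(v0, v_oracle, tolerance = 1e-12)
  # competitive inhibition: rate decreases in NADPH, ATP and 2,3-BPG
  expect_lt(g6pdh_rate(modifyList(base, list(NADPH = 110e-6)), mp), v0)
  mp_atp <- metabolism_params("control", overrides = list(ATP = 2.8e-3))
  expect_lt(g6pdh_rate(base, mp_atp), v0)
  mp_bpg <- metabolism_params("control", overrides = list(BPG = 10e-3))
  expect_lt(g6pdh_rate(base, mp_bpg), v0)
  # the deficient parameter set is far slower under identical conditions
  expect_lt(g6pdh_rate(base, metabolism_params("g6pd")) / v0, 0.1)
})

test_that("hemichrome formation follows the saturable diamide-driven form", {
  mp <- metabolism_params("control")
  KcF <- mp$hemichrome$KcF; KmS <- mp$hemichrome$KmS
  expect_equal(hemichrome_formation_rate(list(diamide = 1e-3, HbO2 = 0), mp), 0)
  expect_equal(hemichrome_formation_rate(list(diamide = 0, HbO2 = 7e-3), mp), 0)
  # half-saturation at HbO2 = KmS
  expect_equal(hemichrome_formation_rate(list(diamide = 1e-3, HbO2 = KmS), mp),
               0.5 * KcF * 1e-3, tolerance = 1e-12)
  # saturation limit KcF * [diamide]
  v_sat <- hemichrome_formation_rate(list(diamide = 1e-3, HbO2 = 1), mp)
  expect_lt(abs(v_sat - KcF * 1e-3) / (KcF * 1e-3), 1e-3)
})

test_that("the diamide-free state is a fixed point of the ODE subsystem", {
  for (v in c("control", "g6pd")) {
    mi <- metabolism_init(metabolism_params(v))
    r <- integrate_metabolism(mi$state, mi$params, 1000)
    conc <- setdiff(names(mi$state), c("I_dia", "I_gsh2", "I_hemi"))
    drift <- abs(r$state[conc] - mi$state[conc]) /
      pmax(abs(mi$state[conc]), 1e-12)
    expect_lt(max(drift), 1e-6)
  }
})

test_that("the isolated diamide-glutathione reaction matches its closed form", {
  # strip the subsystem down to rule 2 by zeroing every other channel
  mp <- metabolism_params("control", overrides = list(
    g6pdh_scale = 0, k_pssg = 0,
    gssgr = list(Vmax = 0, KmGSSG = 60e-6, KmNADPH = 10e-6),
    hemichrome = list(KmS = 1e-4, KcF = 0)))
  mp$k_ox <- 0
  mp$hk$Vmax <- 0
  d0 <- 0.8e-3; g0 <- 2.0e-3; k <- mp$k_diamide_gsh
  state <- c(G6P = 0, NADPH = 0, NADP = 0, GSH = g0, GSSG = 0, PSSG = 0,
             HbO2 = 0, hemichrome = 0, diamide = d0,
             I_dia = 0, I_gsh2 = 0, I_hemi = 0)
  for (tt in c(1, 5, 20)) {
    num <- integrate_metabolism(state, mp, tt)$state
    ana <- oracle_diamide_gsh(d0, g0, k, tt)
    expect_equal(num[["diamide"]], ana$diamide, tolerance = 1e-4)
    expect_equal(num[["GSH"]], ana$GSH, tolerance = 1e-4)
  }
})

test_that("NADP(H) and glutathione moieties are conserved under dosing", {
  mi <- metabolism_init(metabolism_params("control"))
  st <- mi$state
  st[["diamide"]] <- 0.25e-3 / 0.3
  nadp_tot0 <- st[["NADPH"]] + st[["NADP"]]
  gsh_tot0 <- st[["GSH"]] + 2 * st[["GSSG"]] + st[["PSSG"]]
  for (i in 1:20) st <- integrate_metabolism(st, mi$params, 50)$state
  expect_lt(abs(st[["NADPH"]] + st[["NADP"]] - nadp_tot0) / nadp_tot0, 1e-9)
  expect_lt(abs(st[["GSH"]] + 2 * st[["GSSG"]] + st[["PSSG"]] - gsh_tot0) / gsh_tot0,
            1e-6)
})

test_that("GSH transients separate healthy from G6PD-deficient cells", {
  # control: sharp depletion then recovery; G6PD: no recovery within 2 h
  run_gsh <- function(variant) {
    mi <- metabolism_init(metabolism_params(variant))
    st <- mi$state
    st[["diamide"]] <- 0.25e-3 / 0.3
    out <- numeric(0)
    for (tt in seq_len(24)) { # 5-min steps to 120 min
      st <- integrate_metabolism(st, mi$params, 300)$state
      out <- c(out, st[["GSH"]])
    }
    out
  }
  g_ctrl <- run_gsh("control")
  g_def <- run_gsh("g6pd")
  gsh0 <- metabolism_params("control")$init$GSH
  expect_lt(min(g_ctrl) / gsh0, 0.5)          # sharp depletion
  expect_gt(g_ctrl[24] / gsh0, 0.8)           # recovery by 120 min
  expect_lt(g_def[24] / gsh0, 0.5)            # deficient cell stays depleted
  # reducing G6PDH capacity slows recovery monotonically
  mid <- metabolism_params("control", overrides = list(g6pdh_scale = 2e-8))
  mi <- metabolism_init(mid); st <- mi$state
  st[["diamide"]] <- 0.25e-3 / 0.3
  for (tt in seq_len(24)) st <- integrate_metabolism(st, mi$params, 300)$state
  expect_lt(st[["GSH"]], g_ctrl[24])
  expect_gt(st[["GSH"]], g_def[24])
})

test_that("operator-splitting order changes pools by less than the tolerance", {
  mi <- metabolism_init(metabolism_params("control"))
  mp <- mi$params
  st <- mi$state
  st[["diamide"]] <- 0.8e-3
  # ODE step then a pool decrement, vs decrement then ODE step
  dec <- 5 / (band3sim:::AVOGADRO * mp$volume_L)
  a <- integrate_metabolism(st, mp, 0.5)$state
  a[["diamide"]] <- max(0, a[["diamide"]] - dec)
  b <- st; b[["diamide"]] <- max(0, b[["diamide"]] - dec)
  b <- integrate_metabolism(b, mp, 0.5)$state
  expect_lt(abs(a[["GSH"]] - b[["GSH"]]) / b[["GSH"]], 1e-4)
  expect_lt(abs(a[["diamide"]] - b[["diamide"]]) / max(b[["diamide"]], 1e-12), 0.05)
})
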