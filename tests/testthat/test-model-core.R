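test_that("parameter constructors enforce their invariants", {
  expect_error(base_params(alpha = -0.1), "alpha")
  expect_error(base_params(rho = 1.2), "rho")
  expect_error(base_params(l = 3), "exponents")
  expect_error(chimera_params(base_params(), alpha_D = -1), "alpha_D")
  expect_error(chimera_params(base_params(), a = 0.5, variant = "GF"),
               "GF requires")
  expect_error(chimera_params(base_params(), alpha_D = 0.02,
                              variant = "FC"), "FC requires")
  # F pins both donor growth and crowding
  f <- chimera_params(base_params(), variant = "F")
  expect_equal(f$alpha_D, f$base$alpha)
  expect_equal(f$a, 0)
  expect_error(embryo_state(B = -1), "compartments")
})

test_that("base RHS: quiescent and pure-growth limits", {
  quiet <- base_params(alpha = 0, beta = 0, zeta = 0, eta = 0)
  d0 <- base_rhs(embryo_state(B = 8), quiet)
  expect_equal(unname(d0), rep(0, 5))
  grow <- base_params(alpha = 0.07, beta = 0, zeta = 0, eta = 0)
  dg <- base_rhs(embryo_state(B = 8), grow)
  expect_equal(dg[["B"]], 8 * 0.07)
  expect_equal(unname(dg[c("T", "C", "P", "E")]), rep(0, 4))
})

test_that("transition terms cancel: total grows at exactly rate alpha", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_base_params()
    s <- random_state()
    d <- base_rhs(s, p)
    expect_equal(sum(d), p$alpha * state_total(s), tolerance = 1e-12)
  }
})

test_that("base RHS rejects donors and negative states", {
  expect_error(base_rhs(embryo_state(B = 8, D_plus = 2), base_params()),
               "donor")
  s <- c(B = 1, T = -1, C = 0, P = 0, E = 0)
  expect_error(base_rhs(s, base_params()), "negative")
})

test_that("chimera RHS reduces to the base model without donors", {
  set.seed(102)
  for (i in 1:10) {
    bp <- random_base_params()
    cp <- chimera_params(bp, alpha_D = 0.02, a = 2, n = 2L,
                         variant = "GFC")
    s <- random_state()
    d_base <- base_rhs(s, bp)
    d_chi <- chimera_rhs(s, cp)
    expect_equal(d_chi[names(d_base)], d_base, tolerance = 1e-12)
    expect_equal(unname(d_chi[c("D_plus", "D_minus")]), c(0, 0))
  }
})

test_that("without crowding, Fgf4-/- donors are invisible to the host", {
  bp <- base_params()
  cp <- chimera_params(bp, alpha_D = bp$alpha, a = 0, variant = "GF")
  s <- embryo_state(B = 8, D_minus = 10)
  d <- chimera_rhs(s, cp)
  d_host <- base_rhs(embryo_state(B = 8), bp)
  expect_equal(d[names(d_host)], d_host)
  expect_equal(d[["D_minus"]], 10 * bp$alpha)
  # Fgf4+/+ donors, by contrast, feed the PrE induction term
  s2 <- embryo_state(B = 0, C = 5, D_plus = 10)
  d2 <- chimera_rhs(s2, chimera_params(bp, alpha_D = bp$alpha, a = 0,
                                       variant = "GF"))
  expect_gt(d2[["P"]], base_rhs(embryo_state(C = 5), bp)[["P"]])
})

test_that("chimera RHS rejects embryos with both donor genotypes", {
  expect_error(
    chimera_rhs(embryo_state(B = 8, D_plus = 5, D_minus = 5), std_gfc()),
    "one donor genotype")
})

test_that("crowded ICM bias strictly decreases with donor load", {
  rho <- vapply(0:20, function(D) crowded_rho(0.35, 0.5, 1, D),
                numeric(1))
  expect_true(all(diff(rho) < 0))
  rho2 <- vapply(0:20, function(D) crowded_rho(0.35, 0.5, 2, D),
                 numeric(1))
  expect_true(all(diff(rho2) < 0))
  # n = 0 or a = 0 switch crowding off
  expect_equal(crowded_rho(0.35, 0, 1, 15), 0.35)
  expect_equal(crowded_rho(0.35, 0.5, 0, 15), 0.35 / 1.5)
})

test_that("pure growth for 48 h turns 8 cells into ~128", {
  p <- base_params(alpha = log(2) / 12, beta = 0, zeta = 0, eta = 0)
  tr <- solve_embryo(p)
  expect_equal(state_total(trajectory_state(tr, 48)), 128,
               tolerance = 1e-6)
})

test_that("t_max = 0 returns only the initial state", {
  tr <- solve_embryo(base_params(), t_max = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$B, 8)
})

test_that("total cell number follows the closed form 8*exp(alpha*t)", {
  p <- base_params()
  tr <- solve_embryo(p)
  total <- unname(rowSums(tr[, c("B", "T", "C", "P", "E")]))
  expect_equal(total, 8 * exp(p$alpha * tr$t), tolerance = 1e-6)
  # chimera with equal donor growth: total = (8 + D0) * exp(alpha*t)
  cp <- chimera_params(p, alpha_D = p$alpha, a = 1, n = 1L,
                       variant = "FC")
  trc <- solve_embryo(cp, initial = embryo_state(B = 8, D_minus = 10))
  totc <- unname(
    rowSums(trc[, c("B", "T", "C", "P", "E", "D_plus", "D_minus")]))
  expect_equal(totc, 18 * exp(p$alpha * trc$t), tolerance = 1e-6)
})

test_that("solutions stay non-negative from non-negative initials", {
  set.seed(103)
  for (i in 1:8) {
    p <- random_base_params()
    tr <- solve_embryo(p)
    expect_true(all(as.matrix(tr[, c("B", "T", "C", "P", "E")]) >= 0))
  }
})

test_that("adaptive solver matches a fixed-step RK4 oracle", {
  p <- std_base()
  tr <- solve_embryo(p, t_grid = seq(0, 48, 4))
  oracle <- rk4_solve(p, embryo_state(B = 8), 48)
  got <- trajectory_state(tr, 48)[names(oracle)]
  expect_lt(max(abs(got - oracle) / pmax(abs(oracle), 1)), 1e-5)
  cp <- std_gfc()
  trc <- solve_embryo(cp, initial = embryo_state(B = 8, D_minus = 10),
                      t_grid = seq(0, 48, 4))
  oc <- rk4_solve(cp, embryo_state(B = 8, D_minus = 10), 48)
  gotc <- trajectory_state(trc, 48)[names(oc)]
  expect_lt(max(abs(gotc - oc) / pmax(abs(oc), 1)), 1e-5)
})

test_that("chimera trajectory with zero donors reproduces the base one", {
  bp <- std_base()
  cp <- chimera_params(bp, alpha_D = 0.02, a = 0.4, n = 1L,
                       variant = "GFC")
  tr_b <- solve_embryo(bp)
  tr_c <- solve_embryo(cp)
  for (sp in c("B", "T", "C", "P", "E"))
    expect_equal(tr_c[[sp]], tr_b[[sp]], tolerance = 1e-7)
})

test_that("donor crowding monotonically shifts host fates toward TE", {
  cp <- std_gfc(a = 0.2, n = 1L)
  finals <- lapply(c(0, 5, 10, 15), function(d0)
    trajectory_state(solve_embryo(cp,
      initial = embryo_state(B = 8, D_minus = d0)), 48))
  te <- vapply(finals, `[[`, numeric(1), "T")
  icm <- vapply(finals, function(f) f[["C"]] + f[["P"]] + f[["E"]],
                numeric(1))
  expect_true(all(diff(te) > 0))
  expect_true(all(diff(icm) < 0))
})

test_that("asymptotic TE fraction recovers 1 - rho and its edge cases", {
  expect_equal(asymptotic_te_fraction(
    base_params(rho = 0.35, zeta = 0, eta = 0)), 0.65, tolerance = 1e-3)
  expect_equal(asymptotic_te_fraction(
    base_params(rho = 1, zeta = 0, eta = 0)), 0, tolerance = 1e-6)
  expect_equal(asymptotic_te_fraction(
    base_params(rho = 0.5, beta = 10, zeta = 0, eta = 0)), 0.5,
    tolerance = 1e-4)
  expect_error(asymptotic_te_fraction(base_params(beta = 0)), "beta")
  expect_error(asymptotic_te_fraction(base_params(beta = 0.05),
                                      t_max = 10), "not exhausted")
})
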