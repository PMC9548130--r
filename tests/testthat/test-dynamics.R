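test_that("an isolated neuron rests at the leak reversal", {
  p <- quick_params()
  st <- resting_state(single_neuron(), p)
  expect_equal(unname(st$voltages), p$leak_reversal)
  expect_equal(unname(st$thresholds), p$leak_reversal)
})

test_that("a gap-coupled pair with no input rests at the leak reversal", {
  p <- quick_params()
  st <- resting_state(gap_pair(), p)
  expect_equal(unname(st$voltages), rep(p$leak_reversal, 2))
})

test_that("resting state solves the coupled equilibrium system", {
  skip_if_not_installed("pracma")
  con <- chain3()
  p <- quick_params()
  st <- resting_state(con, p)
  # residual of the independently written right-hand side is ~0
  res <- oracle_rhs(con, p, st$voltages, st$activations, st$thresholds)
  expect_lt(max(abs(res)), 1e-9)
  # an independent root-finder from the same ansatz activations agrees
  s_eq <- st$activations
  f <- function(v) oracle_rhs(con, p, v, s_eq, v)[1:3]
  root <- pracma::fsolve(f, rep(-30, 3))$x
  expect_equal(unname(st$voltages), root, tolerance = 1e-6)
})

test_that("zero-stimulus simulation preserves the resting state", {
  con <- chain3()
  p <- quick_params()
  ts <- simulate_network(con, p)
  drift <- abs(ts$voltage - ts$voltage[, 1])
  expect_lt(max(drift), 1e-9)
})

test_that("a single neuron under constant current follows the linear closed form", {
  p <- quick_params()
  i_nA <- 2e-4
  ts <- simulate_network(single_neuron(), p, stimulus_plan(c(A = i_nA)))
  v_ss <- p$leak_reversal + i_nA * 1e6 / p$leak_conductance
  tau <- p$capacitance / p$leak_conductance
  expected <- v_ss + (p$leak_reversal - v_ss) * exp(-ts$time / tau)
  expect_lt(max(abs(ts$voltage["A", ] - expected)), 1e-6 * abs(v_ss - p$leak_reversal))
})

test_that("gap-junction currents cancel pairwise at every sampled state", {
  con <- toy_oscillator()
  p <- quick_params()
  ts <- simulate_network(con, p, stimulus_plan(c(SNL = 0.05, SNR = 0.05)))
  gap_w <- con$gap * p$gap_unit_conductance
  for (k in c(1, 500, 2001)) {
    v <- ts$voltage[, k]
    cur <- gap_w * outer(v, v, `-`)  # cur[i,j] = g_ij (v_i - v_j)
    expect_lt(abs(sum(cur)), 1e-8 * max(1, max(abs(cur))))
  }
})

test_that("identical inputs give bit-identical trace sets", {
  con <- toy_oscillator()
  p <- quick_params()
  stim <- stimulus_plan(c(SNL = 0.05, SNR = 0.05, CM1 = 0.02))
  a <- simulate_network(con, p, stim)
  b <- simulate_network(con, p, stim)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$activation, b$activation)
})

test_that("halving dt changes the solution at fourth-order rates", {
  con <- chain3()
  stim <- stimulus_plan(c(A = 1e-3))
  v_at <- function(dt) {
    ts <- simulate_network(con, model_params(duration = 1, dt = dt), stim)
    ts$voltage["C", ncol(ts$voltage)]
  }
  e1 <- abs(v_at(2e-3) - v_at(5e-4))
  e2 <- abs(v_at(1e-3) - v_at(5e-4))
  expect_lt(e2, e1)               # refining the grid converges
  expect_lt(e2 / max(e1, 1e-300), 0.3)  # faster than first order
})

test_that("mirror-symmetric networks under symmetric stimulus stay symmetric", {
  con <- make_toy_connectome(1, 1, 1, 1, 1, gap_weight = 3, chem_weight = 4,
                             bilateral = TRUE)
  p <- quick_params()
  ts <- simulate_network(con, p, stimulus_plan(c(SN1L = 0.01, SN1R = 0.01)))
  left <- grep("L$", rownames(ts$voltage), value = TRUE)
  right <- sub("L$", "R", left)
  expect_identical(ts$voltage[left, ], unname(ts$voltage[right, ]) |>
                     `rownames<-`(left))
})

test_that("activations stay inside [0, 1]", {
  con <- toy_oscillator()
  p <- quick_params()
  ts <- simulate_network(con, p,
                         stimulus_plan(c(SNL = 0.05, SNR = 0.05,
                                         CM1 = 0.02, CM2 = 0.02, CM3 = 0.02)))
  expect_true(all(ts$activation >= 0 & ts$activation <= 1))
})

test_that("linearized dynamics match the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  p <- model_params(duration = 0.5, dt = 1e-4)
  nets <- list(single = single_neuron(), pair = gap_pair(), chain = chain3())
  # 4-neuron mixed gap+chem net
  nm <- c("A", "B", "C", "D")
  g <- matrix(0, 4, 4, dimnames = list(nm, nm)); g["A", "B"] <- g["B", "A"] <- 4
  ch <- matrix(0, 4, 4, dimnames = list(nm, nm))
  ch["B", "C"] <- 3; ch["C", "D"] <- 2; ch["D", "A"] <- 1
  nets$mixed <- mini_connectome(nm, gap = g, chem = ch,
                                inhibitory = c(FALSE, TRUE, FALSE, FALSE))
  for (con in nets) {
    n <- n_neurons(con)
    stim <- stimulus_plan(setNames(1e-4, con$neurons$name[1]))
    ts <- linearized_simulate(con, p, stim)
    # independent LTI closed form: V' = (-G V + b + I)/C with s frozen
    rest <- resting_state(con, p)
    gap_w <- con$gap * p$gap_unit_conductance
    chem_w <- con$chem * p$syn_unit_conductance
    e_syn <- ifelse(con$neurons$inhibitory, p$syn_reversal_inh,
                    p$syn_reversal_exc)
    cs <- as.vector(crossprod(chem_w, rest$activations))
    cse <- as.vector(crossprod(chem_w, rest$activations * e_syn))
    gmat <- diag(p$leak_conductance + rowSums(gap_w) + cs, n) - gap_w
    amat <- -gmat / p$capacitance
    i_ext <- numeric(n); i_ext[1] <- 1e-4 * 1e6
    b <- (p$leak_conductance * p$leak_reversal + cse + i_ext) / p$capacitance
    v_ss <- solve(gmat, p$leak_conductance * p$leak_reversal + cse + i_ext)
    prop <- as.matrix(Matrix::expm(amat * p$dt))
    v <- rest$voltages
    expected <- matrix(0, n, length(ts$time))
    expected[, 1] <- v
    for (k in 2:length(ts$time)) {
      v <- v_ss + prop %*% (v - v_ss)
      expected[, k] <- v
    }
    expect_lt(max(abs(ts$voltage - expected)), 1e-6)
  }
})

test_that("full and linearized dynamics coincide without chemical synapses", {
  con <- gap_pair()
  p <- quick_params()
  stim <- stimulus_plan(c(A = 1e-3))
  full <- simulate_network(con, p, stim)
  lin <- linearized_simulate(con, p, stim)
  expect_equal(full$voltage, lin$voltage, tolerance = 1e-12)
})

test_that("coarse dt and ablated stimulus targets are rejected or dropped", {
  con <- gap_pair(w = 50)
  expect_error(simulate_network(con, model_params(duration = 1, dt = 0.01)),
               "too coarse")
  con2 <- chain3()
  expect_warning(
    ts <- simulate_network(con2, quick_params(),
                           stimulus_plan(c(A = 1e-3, B = 1e-3)),
                           ablations = "B"),
    "ablated")
  expect_true("B" %in% ts$ablated)
})

test_that("simulation starts from the ablated network's own rest", {
  con <- chain3()
  p <- quick_params()
  abl <- ablate(con, "B")
  ts <- simulate_network(con, p, stimulus_plan(), ablations = "B")
  expect_equal(ts$voltage[, 1], resting_state(abl, p)$voltages)
  drift <- abs(ts$voltage - ts$voltage[, 1])
  expect_lt(max(drift), 1e-9)
})
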