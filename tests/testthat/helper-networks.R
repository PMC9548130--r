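# Small connectomes and parameter sets shared across test files.

neuron_row <- function(name, class = name, category = "inter",
                       inhibitory = FALSE) {
  data.frame(name = name, class = class, category = category,
             inhibitory = inhibitory)
}

# a bare N-neuron connectome from explicit matrices
mini_connectome <- function(names, gap = NULL, chem = NULL,
                            inhibitory = rep(FALSE, length(names)),
                            category = rep("inter", length(names))) {
  n <- length(names)
  z <- matrix(0, n, n, dimnames = list(names, names))
  connectome(
    data.frame(name = names, class = names, category = category,
               inhibitory = inhibitory),
    if (is.null(gap)) z else gap,
    if (is.null(chem)) z else chem)
}

single_neuron <- function() mini_connectome("A")

gap_pair <- function(w = 5) {
  g <- matrix(c(0, w, w, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  mini_connectome(c("A", "B"), gap = g)
}

# A excites B, B inhibits C
chain3 <- function(w = 5) {
  nm <- c("A", "B", "C")
  ch <- matrix(0, 3, 3, dimnames = list(nm, nm))
  ch["A", "B"] <- w; ch["B", "C"] <- w
  mini_connectome(nm, chem = ch, inhibitory = c(FALSE, TRUE, FALSE))
}

quick_params <- function(...) model_params(duration = 2, ...)

# write a connectome's CSV dialect into a temp stem, return the stem
write_temp_connectome <- function(con) {
  stem <- tempfile("con")
  write_connectome(con, stem)
  stem
}

# numeric right-hand side of the model at given state, for oracle use:
# duplicates the published equations independently of the integrator
oracle_rhs <- function(con, params, v, s, thresholds, i_ext_nA = NULL) {
  n <- nrow(con$neurons)
  gap_w <- con$gap * params$gap_unit_conductance
  chem_w <- con$chem * params$syn_unit_conductance
  e_syn <- ifelse(con$neurons$inhibitory, params$syn_reversal_inh,
                  params$syn_reversal_exc)
  i_ext <- numeric(n)
  if (!is.null(i_ext_nA))
    i_ext[match(names(i_ext_nA), con$neurons$name)] <- i_ext_nA * 1e6
  dv <- ds <- numeric(n)
  for (i in seq_len(n)) {
    gap_cur <- sum(gap_w[i, ] * (v[i] - v))
    chem_cur <- sum(chem_w[, i] * s * (v[i] - e_syn))
    dv[i] <- (-params$leak_conductance * (v[i] - params$leak_reversal) -
                gap_cur - chem_cur + i_ext[i]) / params$capacitance
    phi <- 1 / (1 + exp(-params$sigmoid_gain * (v[i] - thresholds[i])))
    ds[i] <- params$syn_rise * phi * (1 - s[i]) - params$syn_decay * s[i]
  }
  c(dv, ds)
}
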