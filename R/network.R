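#' Default leaky-neuron parameters
#'
#' Fast-response rate neurons: time constant 1 ms, steep sigmoid output
#' nonlinearity with slope 8 and offset 0.5 mimicking on-off behaviour.
#'
#' @return List with `tau_s`, `sigmoid_slope`, `sigmoid_offset`.
#' @export
default_neuron_parameters <- function() {
  list(tau_s = 0.001, sigmoid_slope = 8, sigmoid_offset = 0.5)
}

#' The six spinal pathway kinds
#'
#' `IaMN` monosynaptic stretch reflex; `IaINa` disynaptic reciprocal Ia
#' inhibition of antagonists; `IaMNs` heteronymous Ia excitation of
#' synergists; `II` disynaptic static stretch reflex; `Ib` disynaptic
#' autogenic (Golgi tendon) inhibition; `RN` Renshaw recurrent inhibition.
#'
#' @return Character vector of the six pathway names.
#' @export
pathway_kinds <- function() {
  c("IaMN", "IaINa", "IaMNs", "II", "Ib", "RN")
}

#' Neuron output sigmoid
#'
#' Monotone increasing logistic `1 / (1 + exp(-D (x - x0)))`; with the
#' defaults D = 8 and x0 = 0.5 it equals 0.5 at its offset and is near
#' saturation at 0 and 1.
#'
#' @param x input.
#' @param slope steepness D.
#' @param offset midpoint x0.
#' @return Value(s) in (0, 1).
#' @export
neuron_sigmoid <- function(x, slope = 8, offset = 0.5) {
  1 / (1 + exp(-slope * (x - offset)))
}

#' One integration step of a leaky rate neuron
#'
#' `tau rdot = -r + sigmoid(net input)`, advanced with the exact
#' exponential update for the step (the sigmoid of the summed input is held
#' constant over dt), then clamped to \[0, 1\]. Inhibitory inputs enter the
#' sum with negative sign before the sigmoid.
#'
#' @param r current rate(s).
#' @param net_input summed weighted (signed) input(s).
#' @param dt step (s).
#' @param params neuron parameter list.
#' @return Updated rate(s) in \[0, 1\].
#' @export
neuron_step <- function(r, net_input, dt,
                        params = default_neuron_parameters()) {
  stopifnot(dt > 0)
  target <- neuron_sigmoid(net_input, params$sigmoid_slope,
                           params$sigmoid_offset)
  decay <- exp(-dt / params$tau_s)
  pmin(pmax(target + (r - target) * decay, 0), 1)
}

#' Synaptic weight set for the six pathways
#'
#' Per-pathway, per-target-muscle strength of the final connection onto
#' the motoneuron; upstream connections of multi-synaptic pathways are
#' fixed at 1. Pathway sweeps use weights in \[0, 1\]; the synaptic
#' optimisation scenario allows \[0, 2\].
#'
#' @param ... named scalar or per-muscle weights for a subset of
#'   `pathway_kinds()`; unnamed pathways default to 0.
#' @param max_weight upper admissible bound (1 for sweeps, 2 for
#'   optimisation).
#' @return A 6 x 7 numeric matrix (pathway x muscle) of class
#'   `synaptic_weights`.
#' @export
synaptic_weights <- function(..., max_weight = 2) {
  w <- matrix(0, 6, 7, dimnames = list(pathway_kinds(), muscle_names()))
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.matrix(dots[[1]]))
    dots <- NULL
  for (nm in names(dots)) {
    if (!nm %in% pathway_kinds())
      stop("unknown pathway: ", nm)
    val <- dots[[nm]]
    if (length(val) == 1) val <- rep(val, 7)
    w[nm, ] <- val
  }
  if (any(w < 0) || any(w > max_weight))
    stop("synaptic weights must lie in [0, ", max_weight, "]")
  structure(w, class = c("synaptic_weights", "matrix"))
}

#' Minimal spinal-cord preset
#'
#' The reduced spinal model retained after the pathway studies: Ia-MN
#' stretch reflex and Ia-INa reciprocal inhibition at full strength for
#' every muscle, all other pathways absent.
#'
#' @return A `synaptic_weights` matrix.
#' @export
minimal_sc_weights <- function() {
  synaptic_weights(IaMN = 1, IaINa = 1)
}

#' Wire the spinal network from a weight set
#'
#' For each muscle m the motoneuron MN(m) receives: its supraspinal
#' command (weight 1, excitatory); the homonymous Ia afferent (IaMN,
#' excitatory); heteronymous Ia afferents of its synergists (IaMNs,
#' excitatory, each divided by the number of heteronymous connections the
#' MN receives); the II relay interneuron (II, excitatory); inhibition from
#' the Ia interneurons of its antagonists (IaINa); inhibition from its Ib
#' interneuron (Ib); and inhibition from its Renshaw cell (RN), itself
#' driven by MN(m). Upstream (afferent to interneuron, MN to Renshaw)
#' weights are fixed at 1.
#'
#' @param weights `synaptic_weights` matrix.
#' @param relations output of [muscle_relations()].
#' @return List of connection matrices used by the stepper: `w_iamn`,
#'   `w_ii`, `w_ib`, `w_rn` (length-7 vectors), `m_iamns` and `m_iaina`
#'   (7 x 7 matrices mapping source muscle to target MN).
#' @export
build_network <- function(weights, relations = muscle_relations()) {
  stopifnot(inherits(weights, "synaptic_weights") ||
            (is.matrix(weights) && all(dim(weights) == c(6, 7))))
  nm <- muscle_names()
  syn <- relations$synergist_matrix
  ant <- relations$antagonist_matrix
  # m_iamns[target, source]: heteronymous Ia weight divided by in-degree
  indeg <- rowSums(syn)
  m_iamns <- matrix(0, 7, 7, dimnames = list(nm, nm))
  for (m in nm) {
    if (indeg[m] > 0)
      m_iamns[m, syn[m, ]] <- weights["IaMNs", m] / indeg[m]
  }
  # m_iaina[target, source]: inhibition of MN(target) by the Ia
  # interneuron of each antagonist source; final-connection weight is
  # indexed by the target MN.
  m_iaina <- matrix(0, 7, 7, dimnames = list(nm, nm))
  for (m in nm) m_iaina[m, ant[m, ]] <- weights["IaINa", m]
  list(
    w_iamn = stats::setNames(weights["IaMN", ], nm),
    w_ii = stats::setNames(weights["II", ], nm),
    w_ib = stats::setNames(weights["Ib", ], nm),
    w_rn = stats::setNames(weights["RN", ], nm),
    m_iamns = m_iamns,
    m_iaina = m_iaina
  )
}

#' Initial (quiescent) network state
#'
#' All rates start at sigmoid(0), the zero-input fixed point.
#'
#' @param params neuron parameter list.
#' @return List of rate vectors `mn`, `in_ia`, `in_ii`, `in_ib`, `rn`.
#' @export
network_state_init <- function(params = default_neuron_parameters()) {
  r0 <- neuron_sigmoid(0, params$sigmoid_slope, params$sigmoid_offset)
  v <- stats::setNames(rep(r0, 7), muscle_names())
  list(mn = v, in_ia = v, in_ii = v, in_ib = v, rn = v)
}

#' One step of the wired spinal network
#'
#' Steps the interneurons on the delayed afferent inputs and the
#' motoneurons on the summed supraspinal, reflex-excitatory and
#' reflex-inhibitory input; all neurons share the same leaky-sigmoid
#' dynamics. Returns the updated state and the motoneuron rates, which
#' serve as muscle excitations.
#'
#' @param state network state (see [network_state_init()]).
#' @param net wired network from [build_network()].
#' @param ia,ii,ib delayed normalised afferent inputs (length-7 vectors in
#'   \[0, 1\]).
#' @param command supraspinal command per muscle (length-7, \[0, 1\]).
#' @param dt step (s).
#' @param params neuron parameter list.
#' @return List with `state` and `u` (motoneuron rates, length-7).
#' @export
network_step <- function(state, net, ia, ii, ib, command, dt,
                         params = default_neuron_parameters()) {
  mn_input <- command +
    net$w_iamn * ia +
    as.numeric(net$m_iamns %*% ia) +
    net$w_ii * state$in_ii -
    as.numeric(net$m_iaina %*% state$in_ia) -
    net$w_ib * state$in_ib -
    net$w_rn * state$rn
  new_mn <- neuron_step(state$mn, mn_input, dt, params)
  new_in_ia <- neuron_step(state$in_ia, ia, dt, params)
  new_in_ii <- neuron_step(state$in_ii, ii, dt, params)
  new_in_ib <- neuron_step(state$in_ib, ib, dt, params)
  new_rn <- neuron_step(state$rn, state$mn, dt, params)
  state <- list(mn = new_mn, in_ia = new_in_ia, in_ii = new_in_ii,
                in_ib = new_in_ib, rn = new_rn)
  list(state = state, u = new_mn)
}
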