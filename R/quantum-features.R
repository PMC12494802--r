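#' Angle-encoding circuit specification
#'
#' Describes the feature-extraction circuit: for each node, the first
#' \code{n_qubits} embedding dimensions become rotation angles; each qubit q
#' receives RY(theta_q) then RZ(theta_q); a single CNOT chain
#' q0 -> q1 -> ... -> q_{n-1} entangles the register; the readout is the
#' Pauli-Z expectation of every qubit, each value in [-1, 1].
#'
#' Convention: qubit 0 is the most significant bit of the basis-state index
#' (|q0 q1 ... q_{n-1}>).
#'
#' @param n_qubits Number of qubits, 1 to 12 (statevector of at most 4096
#'   amplitudes).
#' @param angle_source Integer vector of embedding columns mapped to angles
#'   (default the first \code{n_qubits}).
#' @param angle_transform \code{"raw"} uses embedding values directly as
#'   radians; \code{"scaled_pi"} rescales each selected column to
#'   [-pi, pi] over the input matrix.
#' @param entangle Apply the CNOT chain (disable to obtain the closed-form
#'   product-state limit <Z_q> = cos(theta_q)).
#' @return A list of class \code{circuit_spec}.
#' @export
circuit_spec <- function(n_qubits = 8L, angle_source = seq_len(n_qubits),
                         angle_transform = c("raw", "scaled_pi"),
                         entangle = TRUE) {
  angle_transform <- match.arg(angle_transform)
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L, n_qubits <= 12L,
            length(angle_source) == n_qubits)
  structure(list(n_qubits = n_qubits, angle_source = as.integer(angle_source),
                 angle_transform = angle_transform, entangle = entangle),
            class = "circuit_spec")
}

#' Initialize the |0...0> statevector
#'
#' @param n_qubits Number of qubits (>= 1).
#' @return Complex amplitude vector of length 2^n_qubits with amplitude 1 at
#'   basis index 0.
#' @export
init_state <- function(n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits < 1L) stop("n_qubits must be >= 1", call. = FALSE)
  s <- complex(2^n_qubits)
  s[1] <- 1 + 0i
  attr(s, "n_qubits") <- n_qubits
  s
}

state_qubits <- function(state) {
  nq <- attr(state, "n_qubits")
  if (is.null(nq)) nq <- as.integer(round(log2(length(state))))
  nq
}

# index pairs for the addressed qubit (0-based qubit, MSB-first convention)
qubit_strides <- function(n_qubits, qubit) {
  if (qubit < 0L || qubit >= n_qubits) stop("invalid qubit index", call. = FALSE)
  stride <- 2L^(n_qubits - 1L - qubit)
  idx <- 0:(2L^n_qubits - 1L)
  i0 <- which(bitwAnd(idx, stride) == 0L)   # 1-based positions with bit = 0
  list(i0 = i0, i1 = i0 + stride)
}

apply_single_qubit_gate <- function(state, qubit, u) {
  nq <- state_qubits(state)
  st <- qubit_strides(nq, qubit)
  a0 <- state[st$i0]; a1 <- state[st$i1]
  state[st$i0] <- u[1, 1] * a0 + u[1, 2] * a1
  state[st$i1] <- u[2, 1] * a0 + u[2, 2] * a1
  state
}

#' Single-qubit rotations
#'
#' \code{apply_ry} applies RY(theta) =
#' [[cos(theta/2), -sin(theta/2)], [sin(theta/2), cos(theta/2)]];
#' \code{apply_rz} applies RZ(theta) = diag(exp(-i theta/2),
#' exp(+i theta/2)) on the addressed qubit. Both preserve the norm.
#'
#' @param state Statevector from [init_state()] or a previous gate.
#' @param qubit 0-based qubit index.
#' @param theta Rotation angle in radians.
#' @return The transformed statevector.
#' @export
apply_ry <- function(state, qubit, theta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  apply_single_qubit_gate(state, qubit, matrix(c(c2, s2, -s2, c2), 2))
}

#' @rdname apply_ry
#' @export
apply_rz <- function(state, qubit, theta) {
  u <- matrix(c(exp(-1i * theta / 2), 0, 0, exp(1i * theta / 2)), 2)
  apply_single_qubit_gate(state, qubit, u)
}

#' Controlled-NOT gate
#'
#' Flips the target bit of every basis state whose control bit is 1.
#'
#' @param state Statevector.
#' @param control,target Distinct 0-based qubit indices.
#' @return The transformed statevector.
#' @export
apply_cnot <- function(state, control, target) {
  if (control == target) stop("control and target must differ", call. = FALSE)
  nq <- state_qubits(state)
  cs <- 2L^(nq - 1L - control); ts <- 2L^(nq - 1L - target)
  if (control < 0L || control >= nq || target < 0L || target >= nq) {
    stop("invalid qubit index", call. = FALSE)
  }
  idx <- 0:(2L^nq - 1L)
  sel <- which(bitwAnd(idx, cs) != 0L & bitwAnd(idx, ts) == 0L)
  swp <- sel + ts
  tmp <- state[sel]
  state[sel] <- state[swp]
  state[swp] <- tmp
  state
}

#' Pauli-Z expectation of one qubit
#'
#' \eqn{\langle Z_q \rangle = \sum_b |a_b|^2 (+1)} if the qubit bit of basis
#' state b is 0, else \eqn{-1}; always in [-1, 1].
#'
#' @param state Statevector.
#' @param qubit 0-based qubit index.
#' @return Real scalar in [-1, 1].
#' @export
pauli_z_expectation <- function(state, qubit) {
  nq <- state_qubits(state)
  st <- qubit_strides(nq, qubit)
  p <- Mod(state)^2
  sum(p[st$i0]) - sum(p[st$i1])
}

resolve_angles <- function(v, spec, column_ranges = NULL) {
  if (length(v) < max(spec$angle_source)) {
    stop("embedding row has fewer dimensions than the circuit needs", call. = FALSE)
  }
  theta <- as.numeric(v[spec$angle_source])
  if (spec$angle_transform == "scaled_pi" && !is.null(column_ranges)) {
    lo <- column_ranges[1, ]; hi <- column_ranges[2, ]
    span <- ifelse(hi > lo, hi - lo, 1)
    theta <- (2 * (theta - lo) / span - 1) * pi
  }
  theta
}

#' Encode one embedding row as a quantum state
#'
#' Initializes |0...0>, applies RY(theta_i) then RZ(theta_i) on each qubit
#' i, then the CNOT chain (if enabled). Deterministic: no sampling noise.
#'
#' @param v Numeric embedding row supplying at least the angle-source
#'   columns.
#' @param spec A [circuit_spec()].
#' @param column_ranges Optional 2 x n_qubits matrix of (min, max) per angle
#'   column, used by the \code{scaled_pi} transform.
#' @return Final statevector.
#' @export
encode_vector <- function(v, spec = circuit_spec(), column_ranges = NULL) {
  theta <- resolve_angles(v, spec, column_ranges)
  state <- init_state(spec$n_qubits)
  for (q in seq_len(spec$n_qubits) - 1L) {
    state <- apply_ry(state, q, theta[q + 1L])
    state <- apply_rz(state, q, theta[q + 1L])
  }
  if (spec$entangle && spec$n_qubits > 1L) {
    for (q in seq_len(spec$n_qubits - 1L) - 1L) {
      state <- apply_cnot(state, q, q + 1L)
    }
  }
  state
}

#' Quantum feature matrix for a set of node embeddings
#'
#' Runs [encode_vector()] on every row and reads out the Pauli-Z expectation
#' of each qubit, yielding an n_nodes x n_qubits matrix of values in
#' [-1, 1] usable as an alternative node representation.
#'
#' @param embeddings n x d matrix with d >= n_qubits.
#' @param spec A [circuit_spec()].
#' @return An \code{embedding_matrix} tagged "QUANTUM".
#' @export
quantum_feature_matrix <- function(embeddings, spec = circuit_spec()) {
  stopifnot(is.matrix(embeddings))
  if (ncol(embeddings) < max(spec$angle_source)) {
    stop("embeddings have fewer columns than the circuit needs", call. = FALSE)
  }
  ranges <- if (spec$angle_transform == "scaled_pi") {
    apply(embeddings[, spec$angle_source, drop = FALSE], 2, range)
  } else NULL
  out <- matrix(NA_real_, nrow(embeddings), spec$n_qubits)
  for (i in seq_len(nrow(embeddings))) {
    st <- encode_vector(embeddings[i, ], spec, ranges)
    out[i, ] <- vapply(seq_len(spec$n_qubits) - 1L,
                       function(q) pauli_z_expectation(st, q), numeric(1))
  }
  rownames(out) <- rownames(embeddings)
  embedding_matrix(out, "QUANTUM")
}
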