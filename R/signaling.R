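#' Normalized Hill activation function
#'
#' Activating interaction of a logic-gated signaling network. The scaling
#' constant `B = (EC50^n - 1)/(2 EC50^n - 1)` enforces f+(0) = 0,
#' f+(1) = W and f+(EC50) = 0.5 W; it is positive only when
#' `EC50^n < 0.5`, which is validated here and at network load time.
#'
#' @param y_j Source node activation (>= 0); vectorized.
#' @param W Reaction weight.
#' @param n Hill coefficient.
#' @param EC50 Half-maximal activation value.
#' @return Activation value(s) in `[0, W]` for inputs in `[0, 1]`.
#' @export
hill_plus <- function(y_j, W = 1, n = 1.4, EC50 = 0.5) {
  if (any(y_j < 0)) stop("hill_plus: y_j must be non-negative", call. = FALSE)
  B <- hill_B(EC50, n)
  W * B * y_j^n / ((B - 1) + y_j^n)
}

#' @rdname hill_plus
#' @export
hill_minus <- function(y_j, W = 1, n = 1.4, EC50 = 0.5) {
  1 - hill_plus(y_j, W, n, EC50)
}

#' Hill scaling constant B
#'
#' @inheritParams hill_plus
#' @return The constant `B` enforcing the normalization constraints.
#' @export
hill_B <- function(EC50, n) {
  stopifnot(EC50 > 0, n > 0)
  e <- EC50^n
  if (e >= 0.5) {
    stop(sprintf(
      "invalid Hill parameters: EC50^n = %.4f >= 0.5 (B would not be positive)",
      e), call. = FALSE)
  }
  (e - 1) / (2 * e - 1)
}

#' Logic gates for combined node influences
#'
#' Scaled logical operators combining two activation values. `gate_and`
#' uses the scaling modification `2ab/(a+b)` (so that AND(x, x) = x);
#' `gate_or` is the probabilistic OR `a + b - ab`; `gate_and_not` takes
#' the activator's f+ and the *inhibitor's* f+ and evaluates
#' `2 f+ (1 - f+_inh) / (f+ + (1 - f+_inh))`. The 0/0 case of the AND
#' gates is defined as 0 by limit.
#'
#' @param fj,fk Activation values of the two influences (f+ scale).
#' @param fk_inhibitor The inhibitor's f+ value (converted internally to
#'   f- = 1 - f+).
#' @return Combined activation value.
#' @export
gate_and <- function(fj, fk) {
  s <- fj + fk
  ifelse(s == 0, 0, 2 * fj * fk / s)
}

#' @rdname gate_and
#' @export
gate_or <- function(fj, fk) fj + fk - fj * fk

#' @rdname gate_and
#' @export
gate_and_not <- function(fj, fk_inhibitor) {
  fm <- 1 - fk_inhibitor
  s <- fj + fm
  ifelse(s == 0, 0, 2 * fj * fm / s)
}

#' Influence-tree constructors
#'
#' A node's influence is an ordered gate tree whose leaves are edges.
#' Composition of the gates is not associative across gate types, so the
#' tree must be declared explicitly; `net_edge()` makes a leaf and
#' `net_gate()` an internal gate node.
#'
#' @param source Source node name.
#' @param W,n,EC50 Hill parameters of the edge.
#' @param sign `"activating"` (evaluates f+) or `"inhibiting"` (f- = 1 - f+).
#' @return A gate-tree node (plain list).
#' @export
net_edge <- function(source, W = 1, n = 1.4, EC50 = 0.5,
                     sign = c("activating", "inhibiting")) {
  sign <- match.arg(sign)
  hill_B(EC50, n)  # validates
  list(gate = "EDGE", source = source, W = W, n = n, EC50 = EC50, sign = sign)
}

#' @rdname net_edge
#' @param gate One of `"AND"`, `"OR"`, `"AND_NOT"`. For `AND_NOT` the
#'   second argument is the inhibitor branch, evaluated on the f+ scale
#'   and complemented inside the gate.
#' @param a,b Sub-trees.
#' @export
net_gate <- function(gate = c("AND", "OR", "AND_NOT"), a, b) {
  gate <- match.arg(gate)
  list(gate = gate, args = list(a, b))
}

eval_tree <- function(tree, y) {
  switch(tree$gate,
    EDGE = {
      f <- hill_plus(y[[tree$source]], tree$W, tree$n, tree$EC50)
      if (tree$sign == "inhibiting") 1 - f else f
    },
    AND = gate_and(eval_tree(tree$args[[1]], y), eval_tree(tree$args[[2]], y)),
    OR = gate_or(eval_tree(tree$args[[1]], y), eval_tree(tree$args[[2]], y)),
    AND_NOT = {
      # inhibitor branch supplies its f+ value; the gate complements it
      fj <- eval_tree(tree$args[[1]], y)
      fk <- eval_tree_plus(tree$args[[2]], y)
      gate_and_not(fj, fk)
    },
    stop("unknown gate type: ", tree$gate, call. = FALSE)
  )
}

# evaluate a branch on the f+ scale regardless of a leaf's declared sign
eval_tree_plus <- function(tree, y) {
  if (tree$gate == "EDGE") {
    hill_plus(y[[tree$source]], tree$W, tree$n, tree$EC50)
  } else {
    eval_tree(tree, y)
  }
}

tree_sources <- function(tree) {
  if (tree$gate == "EDGE") return(tree$source)
  unique(unlist(lapply(tree$args, tree_sources)))
}

validate_tree <- function(tree, node_names, target) {
  if (!is.list(tree) || is.null(tree$gate)) {
    stop("network definition error: malformed gate tree for node '", target,
         "'", call. = FALSE)
  }
  if (tree$gate == "EDGE") {
    if (!tree$source %in% node_names) {
      stop("network definition error: influence on '", target,
           "' references undeclared node '", tree$source, "'", call. = FALSE)
    }
    hill_B(tree$EC50, tree$n)
  } else {
    if (length(tree$args) != 2) {
      stop("network definition error: gate '", tree$gate, "' for node '",
           target, "' must have exactly 2 arguments", call. = FALSE)
    }
    lapply(tree$args, validate_tree, node_names = node_names, target = target)
  }
  invisible(TRUE)
}

#' Construct a logic-gated signaling network
#'
#' @param nodes Data frame with columns `name`, `tau` (time constant),
#'   `y_max` (activity cap), `role` (one of input/internal/output) and
#'   `baseline` (the clamped value for input nodes; ignored otherwise).
#' @param influences Named list mapping each non-input node to its gate
#'   tree (see [net_edge()], [net_gate()]).
#' @return Object of class `gr_network`.
#' @export
signaling_network <- function(nodes, influences) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "tau", "y_max", "role") %in% names(nodes)))
  if (is.null(nodes$baseline)) nodes$baseline <- NA_real_
  if (anyDuplicated(nodes$name)) {
    stop("network definition error: duplicated node names", call. = FALSE)
  }
  stopifnot(all(nodes$tau > 0), all(nodes$y_max >= 0),
            all(nodes$role %in% c("input", "internal", "output")))
  bad <- setdiff(names(influences), nodes$name)
  if (length(bad)) {
    stop("network definition error: influences target undeclared node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(names(influences) %in% nodes$name[nodes$role == "input"])) {
    stop("network definition error: input nodes cannot have influences",
         call. = FALSE)
  }
  for (tg in names(influences)) {
    validate_tree(influences[[tg]], nodes$name, tg)
  }
  inputs <- nodes$name[nodes$role == "input"]
  if (any(is.na(nodes$baseline[nodes$role == "input"]))) {
    stop("network definition error: every input node needs a baseline value",
         call. = FALSE)
  }
  net <- structure(list(nodes = nodes, influences = influences,
                        y0 = NULL), class = "gr_network")
  net$dag <- network_is_dag(net)
  net
}

network_is_dag <- function(net) {
  nm <- net$nodes$name
  deps <- lapply(nm, function(n) {
    tr <- net$influences[[n]]
    if (is.null(tr)) character(0) else tree_sources(tr)
  })
  names(deps) <- nm
  remaining <- nm
  repeat {
    free <- remaining[vapply(remaining, function(n) {
      !any(deps[[n]] %in% remaining)
    }, TRUE)]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  length(remaining) == 0
}

topological_order <- function(net) {
  nm <- net$nodes$name
  deps <- lapply(nm, function(n) {
    tr <- net$influences[[n]]
    if (is.null(tr)) character(0) else tree_sources(tr)
  })
  names(deps) <- nm
  order <- character(0)
  remaining <- nm
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(n) {
      !any(deps[[n]] %in% remaining)
    }, TRUE)]
    if (!length(free)) stop("network contains a cycle", call. = FALSE)
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

#' Right-hand side of the network ODE system
#'
#' `dy_i/ds = (f_i(y) y_max_i - y_i) / tau_i` for non-input nodes; input
#' nodes are clamped to `fixed_inputs` and have zero rate.
#'
#' @param net A [signaling_network()].
#' @param y Named numeric vector of current activations.
#' @param fixed_inputs Named vector of clamped input-node values.
#' @return Named vector `dy/ds`.
#' @export
network_rhs <- function(net, y, fixed_inputs) {
  y[names(fixed_inputs)] <- fixed_inputs
  dy <- numeric(length(y))
  names(dy) <- names(y)
  for (i in seq_len(nrow(net$nodes))) {
    n <- net$nodes$name[i]
    if (net$nodes$role[i] == "input") next
    tr <- net$influences[[n]]
    f <- if (is.null(tr)) 0 else eval_tree(tr, y)
    dy[n] <- (f * net$nodes$y_max[i] - y[n]) / net$nodes$tau[i]
  }
  dy
}

#' Steady state of a signaling network
#'
#' Integrates the network dynamics with clamped inputs until the residual
#' `max |f_i y_max_i - y_i|` falls below `tol`. For acyclic networks the
#' fixed point is obtained exactly by propagating activations in
#' topological order (the default `"auto"` method); the ODE route
#' (`deSolve::lsoda`) is always available and is what `"auto"` falls back
#' to for cyclic graphs.
#'
#' @param net A [signaling_network()].
#' @param fixed_inputs Named vector of input-node values; defaults to the
#'   declared baselines.
#' @param y_init Optional initial activations (named); defaults to 0 for
#'   non-input nodes.
#' @param method `"auto"`, `"propagate"` or `"ode"`.
#' @param tol Residual tolerance (`max |dy/ds| * tau < tol`).
#' @param horizon_factor Safety cap: integration aborts with an error
#'   after `horizon_factor * max(tau)` time units without convergence.
#' @return Named vector of steady-state activations.
#' @export
steady_state <- function(net, fixed_inputs = NULL, y_init = NULL,
                         method = c("auto", "propagate", "ode"),
                         tol = 1e-8, horizon_factor = 1000) {
  method <- match.arg(method)
  nm <- net$nodes$name
  if (is.null(fixed_inputs)) {
    inputs <- net$nodes$role == "input"
    fixed_inputs <- stats::setNames(net$nodes$baseline[inputs],
                                    nm[inputs])
  }
  y <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(y_init)) y[names(y_init)] <- y_init
  y[names(fixed_inputs)] <- fixed_inputs

  if (method == "propagate" || (method == "auto" && isTRUE(net$dag))) {
    ord <- topological_order(net)
    for (n in ord) {
      i <- match(n, nm)
      if (net$nodes$role[i] == "input") next
      tr <- net$influences[[n]]
      f <- if (is.null(tr)) 0 else eval_tree(tr, y)
      y[n] <- f * net$nodes$y_max[i]
    }
    return(y)
  }

  max_tau <- max(net$nodes$tau)
  elapsed <- 0
  chunk <- 20 * max_tau
  repeat {
    res <- network_rhs(net, y, fixed_inputs) * net$nodes$tau[match(nm, nm)]
    if (max(abs(res)) < tol) return(y)
    if (elapsed >= horizon_factor * max_tau) {
      stop(sprintf(
        "steady_state: no steady state within horizon %g (residual %.3e); the network may be oscillatory",
        horizon_factor * max_tau, max(abs(res))), call. = FALSE)
    }
    sol <- deSolve::lsoda(
      y = y, times = c(0, chunk),
      func = function(t, state, parms) {
        state[names(fixed_inputs)] <- fixed_inputs
        list(network_rhs(net, state, fixed_inputs))
      },
      rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    names(y) <- nm
    y[names(fixed_inputs)] <- fixed_inputs
    elapsed <- elapsed + chunk
  }
}

#' Baseline initialization of a network
#'
#' Runs the network to steady state with every input clamped at its
#' declared baseline and stores the resulting activations as `y0`, the
#' reference for normalized output deviations.
#'
#' @param net A [signaling_network()].
#' @param ... Passed to [steady_state()].
#' @return The network with `$y0` set.
#' @export
baseline_init <- function(net, ...) {
  net$y0 <- steady_state(net, ...)
  net
}

#' Sigmoidal scaling of a continuum quantity to a node input
#'
#' `y = 1 / (1 + exp(beta - s_q * dq))` with `dq = (q - q_h)/q_h` and
#' `beta = log((1 - y_i0)/y_i0)` so that the baseline quantity maps to the
#' baseline node input exactly.
#'
#' @param q Continuum quantity (e.g. smooth muscle fiber stress, kPa, or a
#'   concentration).
#' @param q_h Its homeostatic value (non-zero).
#' @param s_q Sensitivity of the node input to relative deviations.
#' @param y_i0 Baseline node input in (0, 1).
#' @return Node input value in (0, 1).
#' @export
scale_input <- function(q, q_h, s_q, y_i0) {
  stopifnot(q_h != 0, y_i0 > 0, y_i0 < 1)
  beta <- log((1 - y_i0) / y_i0)
  dq <- (q - q_h) / q_h
  1 / (1 + exp(beta - s_q * dq))
}

#' Normalized deviation of a signaling output from baseline
#'
#' @param y Current output activation.
#' @param y0 Baseline output activation (> 0).
#' @return `(y - y0)/y0`.
#' @export
delta_psi <- function(y, y0) {
  if (any(y0 <= 0)) {
    stop("delta_psi: undefined baseline (y0 must be positive); re-baseline the network",
         call. = FALSE)
  }
  (y - y0) / y0
}

tree_to_list <- function(tree) {
  if (tree$gate == "EDGE") {
    list(gate = "EDGE", source = tree$source, W = tree$W, n = tree$n,
         EC50 = tree$EC50, sign = tree$sign)
  } else {
    list(gate = tree$gate, args = lapply(tree$args, tree_to_list))
  }
}

list_to_tree <- function(x) {
  if (x$gate == "EDGE") {
    net_edge(x$source, x$W, x$n, x$EC50, x$sign)
  } else {
    net_gate(x$gate, list_to_tree(x$args[[1]]), list_to_tree(x$args[[2]]))
  }
}

#' Read / write a network interchange file
#'
#' JSON dialect with a `nodes` array (name, tau, y_max, role, baseline)
#' and an `influences` object mapping each target to its ordered gate
#' tree. Validation (B positivity, unknown references) happens at load
#' time; the writer emits the same dialect round-trip-stable.
#'
#' @param path File path.
#' @return A `gr_network` (reader) or `path` invisibly (writer).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- do.call(rbind, lapply(x$nodes, function(n) {
    data.frame(name = n$name, tau = n$tau, y_max = n$y_max, role = n$role,
               baseline = if (is.null(n$baseline)) NA_real_ else n$baseline,
               stringsAsFactors = FALSE)
  }))
  influences <- lapply(x$influences, list_to_tree)
  signaling_network(nodes, influences)
}

#' @rdname read_network
#' @param net A `gr_network`.
#' @export
write_network <- function(net, path) {
  x <- list(
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
      n <- net$nodes[i, ]
      out <- list(name = n$name, tau = n$tau, y_max = n$y_max, role = n$role)
      if (!is.na(n$baseline)) out$baseline <- n$baseline
      out
    }),
    influences = lapply(net$influences, tree_to_list)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
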