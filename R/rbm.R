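#' Construct a binary-binary restricted Boltzmann machine
#'
#' The machine has `n_visible` binary visible units (one per lower-triangle
#' contact-map pixel; 4950 for the default 100 x 100 template), `n_hidden`
#' binary hidden units, a weight matrix `W` (visible x hidden), a visible bias
#' `b` and a hidden bias `c`. The energy of a joint configuration is
#' `E(v, h) = -b.v - c.h - v' W h`; lower energy means higher probability.
#' Weights are initialised from a small centred Gaussian (sd 0.01), biases at
#' zero, reproducibly from `seed`.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param weight,visible_bias,hidden_bias optional explicit parameters.
#' @param seed integer seed for the weight initialisation.
#' @return an `rbm_model`.
#' @export
rbm_model <- function(n_visible, n_hidden,
                      weight = NULL, visible_bias = NULL, hidden_bias = NULL,
                      seed = 1L) {
  n_visible <- as.integer(n_visible)
  n_hidden <- as.integer(n_hidden)
  if (is.null(weight)) {
    weight <- with_seed(seed, matrix(rnorm(n_visible * n_hidden, sd = 0.01),
                                     n_visible, n_hidden))
  }
  if (is.null(visible_bias)) visible_bias <- numeric(n_visible)
  if (is.null(hidden_bias)) hidden_bias <- numeric(n_hidden)
  stopifnot(nrow(weight) == n_visible, ncol(weight) == n_hidden,
            length(visible_bias) == n_visible, length(hidden_bias) == n_hidden,
            all(is.finite(weight)), all(is.finite(visible_bias)),
            all(is.finite(hidden_bias)))
  structure(list(weight = weight, visible_bias = visible_bias,
                 hidden_bias = hidden_bias, n_visible = n_visible,
                 n_hidden = n_hidden, rng_seed = as.integer(seed),
                 config = NULL, loss_trace = NULL),
            class = "rbm_model")
}

#' @export
print.rbm_model <- function(x, ...) {
  cat("<rbm_model>", x$n_visible, "visible x", x$n_hidden, "hidden units\n")
  if (!is.null(x$config)) {
    cfg <- x$config
    cat("  trained:", cfg$epochs, "epochs, lr", cfg$learning_rate,
        ", CD-", cfg$cd_k, ", seed ", cfg$seed, "\n", sep = "")
  }
  invisible(x)
}

check_binary <- function(x, what = "vector") {
  if (!all(x %in% c(0, 1))) stop("invalid ", what, ": entries must be 0/1",
                                 call. = FALSE)
  invisible(x)
}

#' Energy of a joint configuration
#'
#' `E(v, h) = -b.v - c.h - v' W h`.
#'
#' @param model an `rbm_model`.
#' @param v binary visible vector.
#' @param h binary hidden vector.
#' @return scalar energy.
#' @export
rbm_energy <- function(model, v, h) {
  if (length(v) != model$n_visible || length(h) != model$n_hidden) {
    stop("dimension error", call. = FALSE)
  }
  -sum(model$visible_bias * v) - sum(model$hidden_bias * h) -
    as.numeric(crossprod(v, model$weight %*% h))
}

#' Conditional activation probabilities
#'
#' Because visible and hidden units only interact across layers, the
#' conditionals factorise: `P(h_j = 1 | v) = logistic(c_j + sum_i W_ij v_i)`
#' and `P(v_i = 1 | h) = logistic(b_i + sum_j W_ij h_j)`. Both accept a single
#' configuration (vector) or a batch (rows of a matrix).
#'
#' @param model an `rbm_model`.
#' @param v,h binary vector or matrix (configurations in rows).
#' @return probability vector / matrix of matching shape.
#' @export
conditional_hidden <- function(model, v) {
  v <- as_batch(v, model$n_visible)
  p <- sigmoid(sweep(v %*% model$weight, 2, model$hidden_bias, `+`))
  drop_batch(p)
}

#' @rdname conditional_hidden
#' @export
conditional_visible <- function(model, h) {
  h <- as_batch(h, model$n_hidden)
  p <- sigmoid(sweep(tcrossprod(h, model$weight), 2, model$visible_bias, `+`))
  drop_batch(p)
}

as_batch <- function(x, n) {
  if (is.matrix(x)) {
    if (ncol(x) != n) stop("dimension error", call. = FALSE)
    x
  } else {
    if (length(x) != n) stop("dimension error", call. = FALSE)
    m <- matrix(as.numeric(x), 1L, n)
    attr(m, "was_vector") <- TRUE
    m
  }
}

drop_batch <- function(p) if (nrow(p) == 1L) as.numeric(p) else p

# all binary states of length n as a 2^n x n matrix (small n only)
enumerate_states <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 1L, 0L))
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(g) <- NULL
  g
}

enumeration_guard <- function(model, limit = 24L) {
  if (model$n_visible + model$n_hidden > limit) {
    stop("enumeration refused: machine too large", call. = FALSE)
  }
}

# free energy F(v) = -b.v - sum_j log(1 + exp(c_j + (W'v)_j)); P(v) ~ exp(-F)
free_energy <- function(model, V) {
  V <- as_batch(V, model$n_visible)
  act <- sweep(V %*% model$weight, 2, model$hidden_bias, `+`)
  # stable softplus: log(1 + e^x) = max(x, 0) + log1p(e^{-|x|})
  softplus <- pmax(act, 0) + log1p(exp(-abs(act)))
  -(V %*% model$visible_bias) - rowSums(softplus)
}

#' Exact partition function of a small machine
#'
#' Sums `exp(-E(v, h))` over all joint states by enumerating visible states
#' and marginalising the hidden layer analytically. Refuses machines with more
#' than 24 total units; intended as a test oracle, not for trained templates.
#'
#' @param model an `rbm_model` with `n_visible + n_hidden <= 24`.
#' @return scalar partition value `z`.
#' @export
exact_partition <- function(model) {
  enumeration_guard(model)
  V <- enumerate_states(model$n_visible)
  sum(exp(-free_energy(model, V)))
}

#' Exact visible distribution of a small machine
#'
#' @param model an enumerable `rbm_model`.
#' @return list with `states` (2^n_visible x n_visible matrix) and `prob`.
#' @export
exact_visible_distribution <- function(model) {
  enumeration_guard(model)
  V <- enumerate_states(model$n_visible)
  w <- exp(-free_energy(model, V))
  list(states = V, prob = as.numeric(w / sum(w)))
}

#' Exact negative log-likelihood of a dataset under a small machine
#'
#' `-(1/N) sum_v log P(v)` with `P(v)` the hidden-marginalised probability;
#' evaluated through the exact partition function.
#'
#' @param model an enumerable `rbm_model`.
#' @param data binary matrix, configurations in rows.
#' @return scalar mean negative log-likelihood (nats).
#' @export
negative_log_likelihood <- function(model, data) {
  data <- as_batch(data, model$n_visible)
  if (nrow(data) == 0L) stop("no samples", call. = FALSE)
  check_binary(data, "data")
  mean(free_energy(model, data)) + log(exact_partition(model))
}

#' Exact likelihood gradient on a small machine (oracle)
#'
#' Ascent direction of the mean log-likelihood: positive phase from the data,
#' negative phase from the enumerated model distribution.
#'
#' @param model an enumerable `rbm_model`.
#' @param data binary matrix of training configurations.
#' @return list with `dW`, `db`, `dc`.
#' @export
exact_gradient <- function(model, data) {
  data <- as_batch(data, model$n_visible)
  check_binary(data, "data")
  ph <- as_batch(conditional_hidden(model, data), model$n_hidden)
  pos_W <- crossprod(data, ph) / nrow(data)
  pos_b <- colMeans(data)
  pos_c <- colMeans(ph)
  dist <- exact_visible_distribution(model)
  phm <- as_batch(conditional_hidden(model, dist$states), model$n_hidden)
  neg_W <- crossprod(dist$states * dist$prob, phm)
  neg_b <- colSums(dist$states * dist$prob)
  neg_c <- colSums(phm * dist$prob)
  list(dW = pos_W - neg_W, db = pos_b - neg_b, dc = pos_c - neg_c)
}

# one stochastic CD-k gradient estimate; binary states in both phases of the
# negative chain, data + hidden probabilities in the positive phase
cd_gradient <- function(model, data, cd_k = 1L) {
  data <- as_batch(data, model$n_visible)
  n <- nrow(data)
  ph_pos <- as_batch(conditional_hidden(model, data), model$n_hidden)
  h <- (matrix(runif(n * model$n_hidden), n) < ph_pos) * 1
  vneg <- data
  for (k in seq_len(cd_k)) {
    pv <- as_batch(conditional_visible(model, h), model$n_visible)
    vneg <- (matrix(runif(n * model$n_visible), n) < pv) * 1
    ph_neg <- as_batch(conditional_hidden(model, vneg), model$n_hidden)
    if (k < cd_k) h <- (matrix(runif(n * model$n_hidden), n) < ph_neg) * 1
  }
  list(dW = (crossprod(data, ph_pos) - crossprod(vneg, ph_neg)) / n,
       db = colMeans(data) - colMeans(vneg),
       dc = colMeans(ph_pos) - colMeans(ph_neg))
}

#' Train an RBM by contrastive divergence
#'
#' Full-batch CD-k by default (training sets here are tens of contact maps):
#' the positive phase uses the data and hidden activation probabilities, the
#' negative phase runs `cd_k` alternating Gibbs steps with binary states. The
#' defaults follow the template-training protocol: learning rate 0.1 and
#' 10,000 epochs; pass smaller `epochs` for quick runs. Training is
#' deterministic given `seed`. A reconstruction-error trace (mean squared
#' difference between the data and the one-step reconstruction) is recorded
#' every `trace_every` epochs.
#'
#' @param data binary matrix (training vectors in rows), a list of 0/1
#'   vectors, or a list of square contact maps (flattened internally).
#' @param n_hidden hidden units (default 100).
#' @param learning_rate SGD step size.
#' @param epochs number of passes.
#' @param cd_k Gibbs steps in the negative phase.
#' @param batch_size minibatch rows; `NULL` = full batch.
#' @param seed RNG seed (initialisation + CD noise).
#' @param trace_every record the loss trace at this epoch interval.
#' @return a trained `rbm_model` with `config` and `loss_trace` filled in.
#' @export
train_rbm <- function(data, n_hidden = 100L, learning_rate = 0.1,
                      epochs = 10000L, cd_k = 1L, batch_size = NULL,
                      seed = 1L, trace_every = max(1L, epochs %/% 200L)) {
  data <- coerce_training_matrix(data)
  if (nrow(data) == 0L) stop("no training data", call. = FALSE)
  check_binary(data, "contact vector")
  nv <- ncol(data)
  model <- rbm_model(nv, n_hidden, seed = seed)
  n <- nrow(data)
  bs <- if (is.null(batch_size)) n else min(as.integer(batch_size), n)
  trace_epoch <- integer(0); trace_err <- numeric(0)
  with_seed(child_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        g <- cd_gradient(model, data[rows, , drop = FALSE], cd_k = cd_k)
        model$weight <- model$weight + learning_rate * g$dW
        model$visible_bias <- model$visible_bias + learning_rate * g$db
        model$hidden_bias <- model$hidden_bias + learning_rate * g$dc
      }
      if (ep %% trace_every == 0L || ep == epochs) {
        ph <- as_batch(conditional_hidden(model, data), n_hidden)
        pv <- as_batch(conditional_visible(model, ph), nv)
        trace_epoch <- c(trace_epoch, ep)
        trace_err <- c(trace_err, mean((data - pv)^2))
      }
    }
  })
  model$config <- list(n_hidden = as.integer(n_hidden),
                       learning_rate = learning_rate,
                       epochs = as.integer(epochs), cd_k = as.integer(cd_k),
                       batch_size = bs, seed = as.integer(seed),
                       n_train = n)
  model$loss_trace <- tibble::tibble(epoch = trace_epoch,
                                     reconstruction_error = trace_err)
  model
}

coerce_training_matrix <- function(data) {
  if (is.list(data)) {
    data <- lapply(data, function(x) {
      if (is.matrix(x)) flatten_map(x) else x
    })
    lens <- vapply(data, length, integer(1))
    if (length(unique(lens)) > 1L) stop("training vectors differ in length",
                                        call. = FALSE)
    data <- do.call(rbind, lapply(data, as.numeric))
  }
  if (!is.matrix(data)) data <- matrix(as.numeric(data), nrow = 1L)
  storage.mode(data) <- "double"
  data
}

#' Gibbs sampling from a trained machine
#'
#' Runs a single alternating chain (`h | v` then `v | h`), discards the first
#' `n_total - n_keep` visible samples as burn-in and keeps the rest. The
#' template protocol generates 10,000 samples and keeps the last 5,000.
#'
#' @param model an `rbm_model`.
#' @param n_total total Gibbs sweeps.
#' @param n_keep samples kept after burn-in (`<= n_total`).
#' @param seed RNG seed.
#' @param init `"random"` or an explicit binary visible vector.
#' @return a `sample_set`: list with `samples` (n_keep x n_visible integer
#'   matrix), `n_total_steps`, `n_kept`.
#' @export
gibbs_sample <- function(model, n_total = 10000L, n_keep = 5000L,
                         seed = 1L, init = "random") {
  stopifnot(inherits(model, "rbm_model"))
  n_total <- as.integer(n_total); n_keep <- as.integer(n_keep)
  if (n_keep > n_total) stop("n_keep must be <= n_total", call. = FALSE)
  nv <- model$n_visible; nh <- model$n_hidden
  kept <- matrix(0L, n_keep, nv)
  with_seed(seed, {
    v <- if (identical(init, "random")) {
      (runif(nv) < 0.5) * 1
    } else {
      if (length(init) != nv) stop("dimension error", call. = FALSE)
      check_binary(init, "init")
      as.numeric(init)
    }
    burn <- n_total - n_keep
    W <- model$weight; b <- model$visible_bias; cc <- model$hidden_bias
    for (step in seq_len(n_total)) {
      ph <- sigmoid(as.numeric(crossprod(W, v)) + cc)
      h <- (runif(nh) < ph) * 1
      pv <- sigmoid(as.numeric(W %*% h) + b)
      v <- (runif(nv) < pv) * 1
      if (step > burn) kept[step - burn, ] <- as.integer(v)
    }
  })
  structure(list(samples = kept, n_total_steps = n_total, n_kept = n_keep),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set>", x$n_kept, "of", x$n_total_steps, "Gibbs samples,",
      ncol(x$samples), "visible units\n")
  invisible(x)
}

#' Contact-frequency template from Gibbs samples
#'
#' The per-pixel mean of the kept samples — the frequency with which each
#' nucleotide pair is in contact across the machine's generated structures —
#' unflattened to a symmetric `template_size` x `template_size` matrix in
#' [0, 1] with a zero diagonal. This is the structural weight `W` that
#' reweights the coupling-analysis scores.
#'
#' @param samples a `sample_set` (or binary sample matrix).
#' @param template_size map size M with `M(M-1)/2` visible units.
#' @return a `template_weight` matrix.
#' @export
contact_weight <- function(samples, template_size = 100L) {
  s <- if (inherits(samples, "sample_set")) samples$samples else samples
  if (is.null(dim(s)) || nrow(s) == 0L) stop("no samples", call. = FALSE)
  M <- as.integer(template_size)
  if (ncol(s) != M * (M - 1L) / 2L) {
    stop("size mismatch: samples have ", ncol(s), " units, expected ",
         M * (M - 1L) / 2L, call. = FALSE)
  }
  freq <- colMeans(s)
  w <- matrix(0, M, M)
  idx <- lower_tri_index(M)
  w[idx] <- freq
  w <- w + t(w)
  structure(w, class = c("template_weight", class(w)))
}

#' @export
print.template_weight <- function(x, ...) {
  cat("<template_weight>", nrow(x), "x", ncol(x),
      sprintf("- mean contact frequency %.3f\n", mean(x[lower.tri(x)])))
  invisible(x)
}

#' @describeIn train_rbm broom-style per-epoch training trace.
#' @param x a trained `rbm_model`.
#' @param ... unused.
#' @export
tidy.rbm_model <- function(x, ...) {
  if (is.null(x$loss_trace)) return(tibble::tibble(epoch = integer(0),
                                                   reconstruction_error = numeric(0)))
  x$loss_trace
}

#' @describeIn train_rbm one-row model summary.
#' @export
glance.rbm_model <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_visible = x$n_visible, n_hidden = x$n_hidden,
    epochs = if (is.null(cfg)) NA_integer_ else cfg$epochs,
    learning_rate = if (is.null(cfg)) NA_real_ else cfg$learning_rate,
    cd_k = if (is.null(cfg)) NA_integer_ else cfg$cd_k,
    final_reconstruction_error = if (is.null(x$loss_trace) ||
                                     nrow(x$loss_trace) == 0L) NA_real_
    else x$loss_trace$reconstruction_error[nrow(x$loss_trace)]
  )
}
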