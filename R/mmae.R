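#' Multimodal autoencoder configuration
#'
#' The autoencoder has a shared narrowing encoder over the concatenated
#' numeric and categorical blocks (default widths 128, 64, 8, the last being
#' the embedding dimension) and a mirrored decoder that splits into two
#' reconstruction heads: a sigmoid head with Bernoulli (binary cross-entropy)
#' loss for the categorical block and a linear head with Gaussian (squared
#' error) loss for the numeric block. Hidden layers use ReLU. Training is by
#' Adam on an 80/20 train/validation split with early stopping on the
#' validation loss (best weights restored).
#'
#' A linear (not ReLU) output is used for the numeric head because the
#' numeric block is standardised and a ReLU output would clip negative
#' values.
#'
#' @param widths encoder layer widths; the last entry is the embedding
#'   dimension.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param validation_fraction held-out fraction for the validation curve.
#' @param loss_weights length-2 multipliers `c(categorical, numeric)` on the
#'   per-column losses of the two modalities. The training objective is the
#'   per-feature weighted mean: each column's Bernoulli or Gaussian loss
#'   counts once, so with the default equal multipliers every feature
#'   contributes equally regardless of how many columns its modality has.
#'   Setting a multiplier to 0 ablates that modality.
#' @param seed seed governing the split, initialisation and batch order.
#' @return A list of class `jip_mmae_config`.
#' @export
mmae_config <- function(widths = c(128L, 64L, 8L), learning_rate = 1e-3,
                        batch_size = 32L, max_epochs = 500L, patience = 20L,
                        validation_fraction = 0.20,
                        loss_weights = c(categorical = 1, numeric = 1),
                        seed = 1L) {
  stopifnot(length(widths) >= 1L, validation_fraction > 0,
            validation_fraction < 1, length(loss_weights) == 2L)
  structure(list(widths = as.integer(widths), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "jip_mmae_config")
}

#' Per-modality reconstruction loss
#'
#' Categorical reconstructions use the mean Bernoulli negative log-likelihood
#' (binary cross-entropy; predictions are clipped to `[1e-7, 1 - 1e-7]` so
#' the loss stays finite at targets 0/1). Numeric reconstructions use mean
#' squared error, the Gaussian negative log-likelihood up to constants.
#'
#' @param reconstruction predicted matrix.
#' @param target observed matrix of the same shape.
#' @param modality `"categorical"` or `"numeric"`.
#' @return Scalar mean loss.
#' @export
modality_loss <- function(reconstruction, target,
                          modality = c("categorical", "numeric")) {
  modality <- match.arg(modality)
  if (!identical(dim(as.matrix(reconstruction)), dim(as.matrix(target)))) {
    stop("shape mismatch between reconstruction and target")
  }
  r <- as.matrix(reconstruction)
  t <- as.matrix(target)
  if (modality == "numeric") return(mean((r - t)^2))
  if (any(r < 0) || any(r > 1)) {
    stop("domain error: categorical reconstruction outside [0, 1]")
  }
  p <- pmin(pmax(r, 1e-7), 1 - 1e-7)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

mmae_forward <- function(par, x, n_num, n_cat) {
  acts <- list(x)
  h <- x
  L <- length(par$W)
  for (l in seq_len(L)) {
    a <- h %*% par$W[[l]] + matrix(par$b[[l]], nrow(h), length(par$b[[l]]),
                                   byrow = TRUE)
    h <- if (l %in% par$relu_layers) relu(a) else a
    acts[[l + 1L]] <- h
  }
  yc <- sigmoid(h %*% par$Wc + matrix(par$bc, nrow(h), length(par$bc),
                                      byrow = TRUE))
  yn <- h %*% par$Wn + matrix(par$bn, nrow(h), length(par$bn), byrow = TRUE)
  list(acts = acts, yc = yc, yn = yn)
}

mmae_loss_parts <- function(fw, xc, xn, w) {
  c(categorical = modality_loss(fw$yc, xc, "categorical"),
    numeric = modality_loss(fw$yn, xn, "numeric"))
}

# gradients of the per-feature weighted reconstruction loss
mmae_backward <- function(par, fw, xc, xn, w) {
  B <- nrow(xc)
  # per-feature weighting: each column counts w[modality] in the objective
  wsum <- sum(w * c(ncol(xc), ncol(xn)))
  gc <- w[1] * (fw$yc - xc) / (B * wsum)           # d BCE/d preact (sigmoid)
  gn <- w[2] * 2 * (fw$yn - xn) / (B * wsum)       # d MSE/d output (linear)
  htop <- fw$acts[[length(fw$acts)]]
  grads <- list(Wc = crossprod(htop, gc), bc = colSums(gc),
                Wn = crossprod(htop, gn), bn = colSums(gn),
                W = vector("list", length(par$W)),
                b = vector("list", length(par$W)))
  delta <- gc %*% t(par$Wc) + gn %*% t(par$Wn)
  for (l in rev(seq_along(par$W))) {
    if (l %in% par$relu_layers) delta <- delta * (fw$acts[[l + 1L]] > 0)
    grads$W[[l]] <- crossprod(fw$acts[[l]], delta)
    grads$b[[l]] <- colSums(delta)
    if (l > 1L) delta <- delta %*% t(par$W[[l]])
  }
  grads
}

#' Train the multimodal autoencoder
#'
#' @param features a `jip_features` matrix from [fit_transform()] with at
#'   least 50 patients and no missing entries.
#' @param config a [mmae_config()].
#' @return An object of class `jip_mmae`: parameters, config, feature column
#'   layout, per-epoch training history (train/validation loss per modality)
#'   and the restored best epoch. The model is frozen: [encode()] is
#'   deterministic.
#' @export
train_mmae <- function(features, config = mmae_config()) {
  stopifnot(inherits(features, "jip_features"),
            inherits(config, "jip_mmae_config"))
  x <- features$x
  if (nrow(x) < 50L) stop("need at least 50 patients to train")
  if (anyNA(x)) stop("feature matrix contains missing entries")
  n_num <- length(features$numeric_cols)
  n_cat <- length(features$categorical_cols)
  xn_all <- x[, features$numeric_cols, drop = FALSE]
  xc_all <- x[, features$categorical_cols, drop = FALSE]

  set.seed(config$seed)
  n <- nrow(x)
  val_idx <- sample.int(n, max(1L, round(config$validation_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)

  # encoder: ncol(x) -> 128 -> 64 -> 8, decoder trunk mirrored: 8 -> 64 -> 128;
  # the embedding layer itself is linear, all other trunk layers ReLU
  dims <- c(ncol(x), config$widths, rev(config$widths[-length(config$widths)]))
  L <- length(dims) - 1L
  par <- list(W = vector("list", L), b = vector("list", L),
              relu_layers = setdiff(seq_len(L), length(config$widths)))
  for (l in seq_len(L)) {
    par$W[[l]] <- he_init(dims[l], dims[l + 1L])
    par$b[[l]] <- numeric(dims[l + 1L])
  }
  top <- dims[L + 1L]
  par$Wc <- he_init(top, n_cat); par$bc <- numeric(n_cat)
  par$Wn <- he_init(top, n_num); par$bn <- numeric(n_num)

  # Adam state mirrors the parameter list
  flat_names <- c(paste0("W", seq_len(L)), paste0("b", seq_len(L)),
                  "Wc", "bc", "Wn", "bn")
  get_par <- function(nm) {
    if (grepl("^W[0-9]", nm)) par$W[[as.integer(sub("W", "", nm))]]
    else if (grepl("^b[0-9]", nm)) par$b[[as.integer(sub("b", "", nm))]]
    else par[[nm]]
  }
  set_par <- function(nm, v) {
    if (grepl("^W[0-9]", nm)) par$W[[as.integer(sub("W", "", nm))]] <<- v
    else if (grepl("^b[0-9]", nm)) par$b[[as.integer(sub("b", "", nm))]] <<- v
    else par[[nm]] <<- v
  }
  adam_m <- lapply(flat_names, function(nm) get_par(nm) * 0)
  adam_v <- adam_m
  names(adam_m) <- names(adam_v) <- flat_names
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L

  w <- config$loss_weights
  wsum <- sum(w * c(n_cat, n_num))      # per-feature weight normaliser
  if (wsum <= 0) stop("loss weights must not both be zero")
  eval_loss <- function(idx) {
    fw <- mmae_forward(par, x[idx, , drop = FALSE], n_num, n_cat)
    parts <- mmae_loss_parts(fw, xc_all[idx, , drop = FALSE],
                             xn_all[idx, , drop = FALSE], w)
    c(parts, total = unname(w[1] * n_cat * parts[1] + w[2] * n_num * parts[2]) / wsum)
  }

  history <- data.frame()
  best <- list(loss = Inf, epoch = 0L, par = par)
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bt in batches) {
      fw <- mmae_forward(par, x[bt, , drop = FALSE], n_num, n_cat)
      if (any(!is.finite(fw$yn))) {
        stop("training error: divergent (non-finite) loss at epoch ", epoch)
      }
      gr <- mmae_backward(par, fw, xc_all[bt, , drop = FALSE],
                          xn_all[bt, , drop = FALSE], w)
      get_gr <- function(nm) {
        if (grepl("^W[0-9]", nm)) gr$W[[as.integer(sub("W", "", nm))]]
        else if (grepl("^b[0-9]", nm)) gr$b[[as.integer(sub("b", "", nm))]]
        else gr[[nm]]
      }
      step <- step + 1L
      for (nm in flat_names) {
        g <- get_gr(nm)
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        set_par(nm, get_par(nm) - config$learning_rate *
                  mhat / (sqrt(vhat) + eps))
      }
    }
    tr <- eval_loss(tr_idx)
    va <- eval_loss(val_idx)
    if (!is.finite(va["total"])) {
      stop("training error: divergent (non-finite) loss at epoch ", epoch)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_categorical = tr["categorical"],
      train_numeric = tr["numeric"], train_total = tr["total"],
      val_categorical = va["categorical"], val_numeric = va["numeric"],
      val_total = va["total"], row.names = NULL))
    if (va["total"] < best$loss - 1e-9) {
      best <- list(loss = va["total"], epoch = epoch, par = par)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- list(par = best$par, config = config,
                layout = colnames(x),
                numeric_cols = features$numeric_cols,
                categorical_cols = features$categorical_cols,
                history = history, best_epoch = best$epoch, frozen = TRUE)
  class(model) <- "jip_mmae"
  model
}

#' @export
print.jip_mmae <- function(x, ...) {
  cat("Multimodal autoencoder: input", length(x$layout), "->",
      paste(x$config$widths, collapse = " -> "),
      sprintf("(embedding dim %d)\n", rev(x$config$widths)[1]))
  cat(sprintf("trained %d epochs, best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_total), x$best_epoch))
  invisible(x)
}

#' Encode patients into the learned embedding
#'
#' Deterministic forward pass through the frozen encoder.
#'
#' @param model a trained `jip_mmae`.
#' @param features a `jip_features` whose columns match the training layout.
#' @return Numeric matrix, patients by embedding dimensions, with patient ids
#'   as row names.
#' @export
encode <- function(model, features) {
  stopifnot(inherits(model, "jip_mmae"), inherits(features, "jip_features"))
  if (!identical(colnames(features$x), model$layout)) {
    diffs <- c(setdiff(model$layout, colnames(features$x)),
               setdiff(colnames(features$x), model$layout))
    stop("feature layout mismatch: ",
         paste(utils::head(diffs, 8L), collapse = ", "))
  }
  h <- features$x
  L_enc <- length(model$config$widths)
  for (l in seq_len(L_enc)) {
    a <- h %*% model$par$W[[l]] +
      matrix(model$par$b[[l]], nrow(h), length(model$par$b[[l]]), byrow = TRUE)
    h <- if (l %in% model$par$relu_layers) relu(a) else a
  }
  rownames(h) <- features$row_ids
  colnames(h) <- paste0("dim", seq_len(ncol(h)))
  h
}
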