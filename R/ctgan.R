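# Conditional tabular GAN for feature-level (layer 2) augmentation.
#
# Continuous columns are encoded by mode-specific normalization: a Gaussian
# mixture is fitted per column, and each value becomes (a scalar normalized
# within its mode, a one-hot mode indicator). The single categorical column
# (the class label) is one-hot encoded and also drives the condition vector
# fed to the generator, sampled during training by log-frequency
# (training-by-sampling). Generator and discriminator are two-hidden-layer
# fully connected networks trained adversarially with the non-saturating
# cross-entropy GAN loss; the generator gets an extra cross-entropy term
# tying its label output to the condition. Backpropagation and the Adam
# updates are implemented directly in R.

MODE_SD_FLOOR <- 1e-6

# Mclust() resolves `mclustBIC` in the caller's environment, so it must be
# importable here for namespace-qualified calls to work.
#' @importFrom mclust Mclust mclustBIC
NULL

#' Fit the mode-specific normalizer of a feature table
#'
#' Fits a Gaussian mixture (up to `max_modes` components, unequal variances,
#' BIC-selected) to every continuous column and records the category list of
#' the label column. Modes with weight below `prune` are dropped and the
#' weights renormalized; a constant column degenerates to a single mode with
#' a floor standard deviation.
#'
#' @param table Feature tibble (numeric columns + `label`).
#' @param max_modes Maximum mixture components per column (default 10).
#' @param prune Minimum mode weight retained (default 0.005).
#' @return A list of class `sleepaug_normalizer`: per-column mixture
#'   parameters and the label categories.
#' @export
fit_mode_normalizer <- function(table, max_modes = 10, prune = 0.005) {
  stopifnot(is.data.frame(table), nrow(table) >= 2, "label" %in% names(table))
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  cols <- list()
  for (cn in num_cols) {
    v <- table[[cn]]
    if (any(!is.finite(v))) abort(sprintf("Column '%s' has non-finite values.", cn),
                                  class = "sleepaug_input_error")
    if (stats::sd(v) < MODE_SD_FLOOR) {
      cols[[cn]] <- list(weights = 1, means = mean(v), sds = MODE_SD_FLOOR)
      next
    }
    fit <- tryCatch(
      suppressWarnings(Mclust(v, G = seq_len(max_modes),
                              modelNames = "V", verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) {
      cols[[cn]] <- list(weights = 1, means = mean(v), sds = max(stats::sd(v), MODE_SD_FLOOR))
      next
    }
    w <- fit$parameters$pro
    mu <- fit$parameters$mean
    sd_ <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd_) == 1) sd_ <- rep(sd_, length(mu))
    keep <- w >= prune
    if (!any(keep)) keep <- which.max(w)
    w <- w[keep] / sum(w[keep])
    cols[[cn]] <- list(weights = as.numeric(w), means = as.numeric(mu[keep]),
                       sds = pmax(as.numeric(sd_[keep]), MODE_SD_FLOOR))
  }
  structure(list(columns = cols,
                 categories = sort(unique(as.character(table$label)))),
            class = "sleepaug_normalizer")
}

mode_posterior <- function(v, col) {
  d <- vapply(seq_along(col$weights), function(k) {
    col$weights[k] * stats::dnorm(v, col$means[k], col$sds[k])
  }, numeric(length(v)))
  d <- matrix(d, nrow = length(v))
  rs <- rowSums(d)
  zero <- rs <= 0
  if (any(zero)) {           # far outlier: nearest-mean assignment
    nm <- vapply(v[zero], function(x) which.min(abs(x - col$means)), integer(1))
    d[zero, ] <- 0
    d[cbind(which(zero), nm)] <- 1
    rs[zero] <- 1
  }
  d / rs
}

#' Encode / decode a value under the mode-specific normalizer
#'
#' `normalizer_encode()` maps a value of one continuous column to its mode
#' index (maximum-posterior assignment) and the within-mode normalized scalar
#' `(v - mu_k) / (4 sd_k)`; `normalizer_decode()` inverts it exactly.
#'
#' @param norm A `sleepaug_normalizer`.
#' @param column Column name.
#' @param v Numeric values.
#' @param alpha,mode Encoded scalar and mode index (for decode).
#' @return `normalizer_encode()`: list with `alpha` and `mode`;
#'   `normalizer_decode()`: numeric values.
#' @export
normalizer_encode <- function(norm, column, v) {
  col <- norm$columns[[column]]
  if (is.null(col)) abort(sprintf("Unknown column '%s'.", column),
                          class = "sleepaug_input_error")
  post <- mode_posterior(v, col)
  mode <- max.col(post, ties.method = "first")
  alpha <- (v - col$means[mode]) / (4 * col$sds[mode])
  list(alpha = alpha, mode = mode)
}

#' @rdname normalizer_encode
#' @export
normalizer_decode <- function(norm, column, alpha, mode) {
  col <- norm$columns[[column]]
  col$means[mode] + 4 * col$sds[mode] * alpha
}

# --- tiny MLP machinery -----------------------------------------------------

mlp_init <- function(sizes, seed_offset = 0) {
  layers <- list()
  for (i in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1]),
      b = numeric(sizes[i + 1]))
  }
  layers
}

lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
lrelu_grad <- function(x, a = 0.2) ifelse(x > 0, 1, a)

mlp_forward <- function(layers, X, act = "relu") {
  hs <- list(X)
  zs <- list()
  L <- length(layers)
  for (i in seq_len(L)) {
    Z <- sweep(hs[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, `+`)
    zs[[i]] <- Z
    hs[[i + 1]] <- if (i < L) {
      if (act == "relu") pmax(Z, 0) else lrelu(Z)
    } else Z
  }
  list(out = hs[[length(hs)]], hs = hs, zs = zs)
}

# dOut: gradient wrt the (linear) output. Returns list(grads, dX).
mlp_backward <- function(layers, cache, dOut, act = "relu") {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(cache$hs[[i]], delta),
                       b = colSums(delta))
    if (i > 1) {
      dH <- delta %*% t(layers[[i]]$W)
      Z <- cache$zs[[i - 1]]
      dZ <- if (act == "relu") dH * (Z > 0) else dH * lrelu_grad(Z)
      delta <- dZ
    } else {
      dX <- delta %*% t(layers[[1]]$W)
    }
  }
  list(grads = grads, dX = dX)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_update <- function(layers, grads, state, t, lr = 2e-4,
                        beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  for (i in seq_along(layers)) {
    state[[i]]$mW <- beta1 * state[[i]]$mW + (1 - beta1) * grads[[i]]$W
    state[[i]]$vW <- beta2 * state[[i]]$vW + (1 - beta2) * grads[[i]]$W^2
    state[[i]]$mb <- beta1 * state[[i]]$mb + (1 - beta1) * grads[[i]]$b
    state[[i]]$vb <- beta2 * state[[i]]$vb + (1 - beta2) * grads[[i]]$b^2
    mhW <- state[[i]]$mW / (1 - beta1^t); vhW <- state[[i]]$vW / (1 - beta2^t)
    mhb <- state[[i]]$mb / (1 - beta1^t); vhb <- state[[i]]$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
  }
  list(layers = layers, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# --- encoding layout --------------------------------------------------------

ctgan_layout <- function(norm) {
  cols <- names(norm$columns)
  idx <- list()
  pos <- 0L
  for (cn in cols) {
    K <- length(norm$columns[[cn]]$weights)
    idx[[cn]] <- list(alpha = pos + 1L, modes = pos + 1L + seq_len(K))
    pos <- pos + 1L + K
  }
  n_cat <- length(norm$categories)
  label <- pos + seq_len(n_cat)
  list(cols = idx, label = label, width = pos + n_cat)
}

encode_rows <- function(table, norm, layout, sample_modes = TRUE) {
  n <- nrow(table)
  X <- matrix(0, n, layout$width)
  for (cn in names(norm$columns)) {
    col <- norm$columns[[cn]]
    v <- table[[cn]]
    post <- mode_posterior(v, col)
    mode <- if (sample_modes && ncol(post) > 1) {
      apply(post, 1, function(p) sample.int(length(p), 1, prob = p))
    } else max.col(post, ties.method = "first")
    alpha <- pmin(pmax((v - col$means[mode]) / (4 * col$sds[mode]), -1), 1)
    X[, layout$cols[[cn]]$alpha] <- alpha
    X[cbind(seq_len(n), layout$cols[[cn]]$modes[mode])] <- 1
  }
  lab <- match(as.character(table$label), norm$categories)
  X[cbind(seq_len(n), layout$label[lab])] <- 1
  X
}

# Generator raw output -> encoded row (tanh alphas, softmax mode and label
# blocks). Returns the row matrix plus caches for backprop.
g_output_transform <- function(O, layout) {
  X <- O
  caches <- list()
  for (cn in names(layout$cols)) {
    ia <- layout$cols[[cn]]$alpha
    im <- layout$cols[[cn]]$modes
    X[, ia] <- tanh(O[, ia])
    if (length(im) > 1) X[, im] <- softmax_rows(O[, im, drop = FALSE])
    else X[, im] <- 1
  }
  il <- layout$label
  X[, il] <- softmax_rows(O[, il, drop = FALSE])
  X
}

# Gradient of loss wrt generator raw output O, given gradient wrt the
# transformed row X (and the transformed values).
g_output_backward <- function(dX, X, layout) {
  dO <- dX
  for (cn in names(layout$cols)) {
    ia <- layout$cols[[cn]]$alpha
    im <- layout$cols[[cn]]$modes
    dO[, ia] <- dX[, ia] * (1 - X[, ia]^2)
    if (length(im) > 1) {
      P <- X[, im, drop = FALSE]
      G <- dX[, im, drop = FALSE]
      dO[, im] <- P * (G - rowSums(P * G))
    } else dO[, im] <- 0
  }
  il <- layout$label
  P <- X[, il, drop = FALSE]
  G <- dX[, il, drop = FALSE]
  dO[, il] <- P * (G - rowSums(P * G))
  dO
}

# --- training ---------------------------------------------------------------

#' Train the conditional tabular GAN on a feature table
#'
#' Adversarial training with training-by-sampling: each step draws condition
#' categories with probability proportional to `log(1 + count)`, picks
#' matching real rows, and trains the discriminator (real vs generated, both
#' concatenated with the condition vector) and the generator (non-saturating
#' adversarial loss plus cross-entropy between its label output and the
#' condition). Deterministic for a fixed seed.
#'
#' @param table Feature tibble: numeric columns + `label` (two or more
#'   categories). Non-numeric columns other than `label` are ignored.
#' @param epochs Training epochs (default 2000).
#' @param batch Batch size (default `min(500, nrow(table))`).
#' @param seed Integer seed.
#' @param latent_dim,hidden Generator/discriminator sizes (defaults 128 and
#'   c(256, 256)).
#' @param max_modes Passed to [fit_mode_normalizer()].
#' @param lr Adam learning rate (default 1e-3; the reference CTGAN's 2e-4
#'   under-converges within the few thousand steps these small tables get).
#' @param fm_weight Weight of the condition-wise feature-matching term:
#'   squared differences between the generated batch's first two
#'   encoded-column moments and the training set's conditional moments,
#'   added to the generator loss. Adversarial-only training
#'   (`fm_weight = 0`) oscillates on small tables.
#' @return A list of class `sleepaug_ctgan` (networks, normalizer, layout,
#'   schema, loss history).
#' @export
ctgan_fit <- function(table, epochs = 2000, batch = NULL, seed = 1L,
                      latent_dim = 128, hidden = c(256, 256),
                      max_modes = 10, lr = 1e-3, fm_weight = 10) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(batch)) batch <- min(500L, nrow(table))
  if (nrow(table) < batch) abort("Fewer rows than the batch size.",
                                 class = "sleepaug_input_error")
  norm <- fit_mode_normalizer(table, max_modes = max_modes)
  layout <- ctgan_layout(norm)
  n_cond <- length(norm$categories)
  lab <- as.character(table$label)
  counts <- table(factor(lab, levels = norm$categories))
  cond_probs <- log(1 + as.numeric(counts))
  cond_probs <- cond_probs / sum(cond_probs)
  rows_by_cat <- lapply(norm$categories, function(cg) which(lab == cg))
  Xreal_all <- encode_rows(table, norm, layout, sample_modes = TRUE)
  # fixed conditional moment targets for feature matching (a per-batch target
  # would itself carry sampling noise of the order of the tolerance aimed at)
  cond_moments <- lapply(rows_by_cat, function(idx) {
    Xk <- Xreal_all[idx, , drop = FALSE]
    list(m = colMeans(Xk), q = colMeans(Xk^2))
  })

  G <- mlp_init(c(latent_dim + n_cond, hidden, layout$width))
  D <- mlp_init(c(layout$width + n_cond, hidden, 1))
  stG <- adam_init(G); stD <- adam_init(D)
  t_adam <- 0L
  steps <- max(1L, nrow(table) %/% batch)
  hist_d <- hist_g <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    dl <- gl <- 0
    for (s in seq_len(steps)) {
      t_adam <- t_adam + 1L
      cond_idx <- sample.int(n_cond, batch, replace = TRUE, prob = cond_probs)
      Cmat <- matrix(0, batch, n_cond)
      Cmat[cbind(seq_len(batch), cond_idx)] <- 1
      ridx <- vapply(cond_idx, function(k) {
        pool <- rows_by_cat[[k]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      Xr <- Xreal_all[ridx, , drop = FALSE]

      Z <- matrix(stats::rnorm(batch * latent_dim), batch)
      gf <- mlp_forward(G, cbind(Z, Cmat), act = "relu")
      Xf <- g_output_transform(gf$out, layout)

      # discriminator step
      df_r <- mlp_forward(D, cbind(Xr, Cmat), act = "lrelu")
      df_f <- mlp_forward(D, cbind(Xf, Cmat), act = "lrelu")
      sr <- df_r$out[, 1]; sf <- df_f$out[, 1]
      d_loss <- mean(softplus(-sr)) + mean(softplus(sf))
      gr_r <- mlp_backward(D, df_r,
                           matrix(-stats::plogis(-sr) / batch), act = "lrelu")
      gr_f <- mlp_backward(D, df_f,
                           matrix(stats::plogis(sf) / batch), act = "lrelu")
      gD <- lapply(seq_along(D), function(i) list(
        W = gr_r$grads[[i]]$W + gr_f$grads[[i]]$W,
        b = gr_r$grads[[i]]$b + gr_f$grads[[i]]$b))
      up <- adam_update(D, gD, stD, t_adam, lr = lr)
      D <- up$layers; stD <- up$state

      # generator step (fresh noise)
      Z <- matrix(stats::rnorm(batch * latent_dim), batch)
      gf <- mlp_forward(G, cbind(Z, Cmat), act = "relu")
      Xf <- g_output_transform(gf$out, layout)
      df_f <- mlp_forward(D, cbind(Xf, Cmat), act = "lrelu")
      sf <- df_f$out[, 1]
      p_lab <- Xf[, layout$label, drop = FALSE]
      ce <- -mean(log(pmax(p_lab[cbind(seq_len(batch), cond_idx)], 1e-12)))
      # condition-wise feature matching on the first two moments of the
      # encoded columns (stabilizes the oscillation-prone adversarial updates
      # and teaches the generator the class-conditional column shifts)
      fm <- 0
      dFM <- matrix(0, batch, layout$width)
      for (k in unique(cond_idx)) {
        idx <- which(cond_idx == k)
        nk <- length(idx)
        dm <- colMeans(Xf[idx, , drop = FALSE]) - cond_moments[[k]]$m
        dq <- colMeans(Xf[idx, , drop = FALSE]^2) - cond_moments[[k]]$q
        fm <- fm + (nk / batch) * (sum(dm^2) + sum(dq^2))
        dFM[idx, ] <- (matrix(2 * dm, nk, layout$width, byrow = TRUE) +
                         4 * Xf[idx, , drop = FALSE] *
                           matrix(dq, nk, layout$width, byrow = TRUE)) / batch
      }
      fm <- fm_weight * fm
      g_loss <- mean(softplus(-sf)) + ce + fm
      back_d <- mlp_backward(D, df_f,
                             matrix(-stats::plogis(-sf) / batch), act = "lrelu")
      dXf <- back_d$dX[, seq_len(layout$width), drop = FALSE]
      dXf <- dXf + fm_weight * dFM
      dXf[, layout$label] <- dXf[, layout$label] -
        Cmat / pmax(p_lab, 1e-12) / batch
      dO <- g_output_backward(dXf, Xf, layout)
      back_g <- mlp_backward(G, gf, dO, act = "relu")
      up <- adam_update(G, back_g$grads, stG, t_adam, lr = lr)
      G <- up$layers; stG <- up$state

      if (!is.finite(d_loss) || !is.finite(g_loss)) {
        abort(sprintf("GAN training diverged at epoch %d.", ep),
              class = "sleepaug_training_diverged_error")
      }
      dl <- dl + d_loss / steps; gl <- gl + g_loss / steps
    }
    hist_d[ep] <- dl; hist_g[ep] <- gl
  }

  structure(list(
    G = G, D = D, normalizer = norm, layout = layout,
    latent_dim = latent_dim, categories = norm$categories,
    cond_freq = as.numeric(counts) / sum(counts),
    schema = names(table),
    numeric_cols = names(norm$columns),
    config = list(epochs = epochs, batch = batch, seed = seed, lr = lr),
    loss = tibble::tibble(epoch = seq_len(epochs), d_loss = hist_d,
                          g_loss = hist_g)),
    class = "sleepaug_ctgan")
}

#' Sample synthetic feature rows from a trained CTGAN
#'
#' Draws condition categories (from the training label frequencies, or a
#' fixed `condition`), generates encoded rows, and keeps those whose decoded
#' label agrees with the drawn condition (rejection/resampling), so
#' conditional sampling is 100% condition-compliant. Decoding inverts the
#' mode-specific normalization: the mode is sampled from the generated mode
#' probabilities and the scalar mapped back through the mode's mean and SD.
#'
#' @param model A `sleepaug_ctgan`.
#' @param n Number of rows (default 10000).
#' @param condition Optional label category all rows must carry.
#' @param seed Integer seed.
#' @return Tibble with the training schema; `subject_id` is `NA` and
#'   `provenance` is `"ctgan"` when those columns exist in the schema.
#' @export
ctgan_sample <- function(model, n = 10000, condition = NULL, seed = 1L) {
  stopifnot(inherits(model, "sleepaug_ctgan"), n >= 1)
  if (!is.null(condition) && !condition %in% model$categories) {
    abort(sprintf("Unknown condition category '%s'.", condition),
          class = "sleepaug_input_error")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  layout <- model$layout
  n_cond <- length(model$categories)
  got_rows <- list(); got_lab <- list(); got <- 0L
  guard <- 0L
  while (got < n) {
    guard <- guard + 1L
    if (guard > 10000L) abort("Condition rejection failed to converge.",
                              class = "sleepaug_input_error")
    b <- min(512L, max(64L, n - got))
    cond_idx <- if (is.null(condition)) {
      sample.int(n_cond, b, replace = TRUE, prob = model$cond_freq)
    } else rep(match(condition, model$categories), b)
    Cmat <- matrix(0, b, n_cond)
    Cmat[cbind(seq_len(b), cond_idx)] <- 1
    Z <- matrix(stats::rnorm(b * model$latent_dim), b)
    Xf <- g_output_transform(mlp_forward(model$G, cbind(Z, Cmat))$out, layout)
    lab_hat <- max.col(Xf[, layout$label, drop = FALSE], ties.method = "first")
    keep <- which(lab_hat == cond_idx)
    if (!length(keep)) next
    keep <- keep[seq_len(min(length(keep), n - got))]
    got_rows[[length(got_rows) + 1L]] <- Xf[keep, , drop = FALSE]
    got_lab[[length(got_lab) + 1L]] <- lab_hat[keep]
    got <- got + length(keep)
  }
  X <- do.call(rbind, got_rows)
  labs <- model$categories[unlist(got_lab)]
  out <- list()
  for (cn in model$numeric_cols) {
    col <- model$normalizer$columns[[cn]]
    im <- layout$cols[[cn]]$modes
    K <- length(im)
    mode <- if (K > 1) {
      apply(X[, im, drop = FALSE], 1, function(p) {
        sample.int(K, 1, prob = pmax(p, 1e-12))
      })
    } else rep(1L, nrow(X))
    alpha <- pmin(pmax(X[, layout$cols[[cn]]$alpha], -1), 1)
    out[[cn]] <- normalizer_decode(model$normalizer, cn, alpha, mode)
  }
  res <- tibble::as_tibble(out)
  res$label <- labs
  if ("subject_id" %in% model$schema) res$subject_id <- NA_character_
  if ("provenance" %in% model$schema) res$provenance <- "ctgan"
  res[, model$schema[model$schema %in% names(res)]]
}

#' Compare a synthetic feature table against the real one
#'
#' Per-column agreement report in the style used to validate tabular GAN
#' output: real and synthetic mean and SD with absolute differences, the
#' Frobenius norm of the difference between the two correlation matrices,
#' and pass flags against configurable tolerances.
#'
#' @param real,fake Feature tibbles with identical numeric schema.
#' @param tol_mean Allowed `|mean_fake - mean_real|` in units of the real
#'   column SD (default 0.25).
#' @param tol_sd Allowed `|sd_fake - sd_real|` in units of the real SD
#'   (default 0.5).
#' @return A list of class `sleepaug_gan_validation`: `columns` tibble,
#'   `corr_frobenius`, `pass`.
#' @export
validate_synthetic <- function(real, fake, tol_mean = 0.25, tol_sd = 0.5) {
  num <- names(real)[vapply(real, is.numeric, logical(1))]
  if (!identical(num, names(fake)[vapply(fake, is.numeric, logical(1))])) {
    abort("Real and synthetic tables have different numeric schemas.",
          class = "sleepaug_input_error")
  }
  cols <- purrr::map_dfr(num, function(cn) {
    mr <- mean(real[[cn]]); mf <- mean(fake[[cn]])
    sr <- stats::sd(real[[cn]]); sf <- stats::sd(fake[[cn]])
    tibble::tibble(column = cn, mean_real = mr, mean_fake = mf,
                   std_real = sr, std_fake = sf,
                   mean_abs_diff = abs(mf - mr), std_abs_diff = abs(sf - sr),
                   pass = abs(mf - mr) <= tol_mean * max(sr, MODE_SD_FLOOR) &
                     abs(sf - sr) <= tol_sd * max(sr, MODE_SD_FLOOR))
  })
  cr <- stats::cor(real[num]); cf <- stats::cor(fake[num])
  cr[!is.finite(cr)] <- 0; cf[!is.finite(cf)] <- 0
  frob <- sqrt(sum((cr - cf)^2))
  structure(list(columns = cols, corr_frobenius = frob, pass = all(cols$pass)),
            class = "sleepaug_gan_validation")
}

#' Save / load a trained CTGAN
#'
#' @param model A `sleepaug_ctgan`.
#' @param path Archive file path.
#' @return `ctgan_save()` the path invisibly; `ctgan_load()` the model.
#' @export
ctgan_save <- function(model, path) {
  stopifnot(inherits(model, "sleepaug_ctgan"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname ctgan_save
#' @export
ctgan_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sleepaug_ctgan"))
  model
}

#' @export
tidy.sleepaug_ctgan <- function(x, ...) x$loss

#' @export
glance.sleepaug_ctgan <- function(x, ...) {
  tibble::tibble(
    epochs = x$config$epochs, batch = x$config$batch, seed = x$config$seed,
    encoded_width = x$layout$width,
    final_d_loss = utils::tail(x$loss$d_loss, 1),
    final_g_loss = utils::tail(x$loss$g_loss, 1))
}

#' @export
tidy.sleepaug_gan_validation <- function(x, ...) x$columns

#' @export
glance.sleepaug_gan_validation <- function(x, ...) {
  tibble::tibble(n_columns = nrow(x$columns),
                 n_flagged = sum(!x$columns$pass),
                 corr_frobenius = x$corr_frobenius, pass = x$pass)
}

#' @export
print.sleepaug_gan_validation <- function(x, ...) {
  cat(sprintf(
    "<sleepaug_gan_validation> %d columns, %d flagged, corr Frobenius %.3f, %s\n",
    nrow(x$columns), sum(!x$columns$pass), x$corr_frobenius,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
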