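# Pixel-wise RGB -> CIELAB reflectance prediction with a perceptually
# balanced color loss.
#
# The network is a compact encoder-decoder: a global context encoder pools
# the image to a coarse grid and maps it through a small MLP to a scene code
# (in a diagonal illumination world the code has to carry the illuminant);
# the decoder maps each pixel's log-RGB, concatenated with the scene code
# (an input skip connection), to a Lab reflectance triple. Training uses
# hand-rolled backpropagation with Adam; the perceptual CIEDE2000 term is
# differentiated by forward finite differences on the predicted Lab values.

#' Parameters of the perceptually balanced color loss
#'
#' The loss combines a CIEDE2000 term, a chroma-weighted squared error on the
#' chromatic channels, and a squared lightness term:
#' `lambda1 * mean(dE00) + lambda2 * mean(w * ((a_p - a_gt)^2 +
#' (b_p - b_gt)^2)) + lambda3 * mean((L_p - L_gt)^2)`, where the per-pixel
#' chroma weight `w = 1 + beta * (C_gt / chroma_norm)^gamma` amplifies the
#' penalty on rare saturated pixels so the model cannot minimize risk by
#' desaturating its output.
#'
#' @param lambda1,lambda2,lambda3 Non-negative term weights
#'   (defaults 1, 0.5, 0.2).
#' @param beta Chroma-weight strength (default 2).
#' @param gamma Chroma-weight shape (default 2).
#' @param chroma_norm Chroma normalization constant (fixed at 128).
#' @return Object of class `pbc_params`.
#' @export
pbc_params <- function(lambda1 = 1, lambda2 = 0.5, lambda3 = 0.2,
                       beta = 2, gamma = 2, chroma_norm = 128) {
  vals <- c(lambda1, lambda2, lambda3, beta, gamma)
  if (any(!is.finite(vals)) || any(vals < 0) || chroma_norm <= 0) {
    stop("loss weights must be non-negative and chroma_norm positive",
         call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 beta = beta, gamma = gamma, chroma_norm = chroma_norm),
            class = "pbc_params")
}

#' Per-pixel chroma weighting factor
#'
#' `w = 1 + beta * (C_gt / chroma_norm)^gamma`; equals 1 for achromatic
#' ground truth and grows monotonically with ground-truth chroma.
#'
#' @param C_gt Ground-truth chroma values (>= 0), vectorized.
#' @param params A [pbc_params()] object.
#' @return Weights >= 1, same length as `C_gt`.
#' @export
chroma_weight <- function(C_gt, params = pbc_params()) {
  stopifnot(inherits(params, "pbc_params"))
  if (any(C_gt < 0)) stop("chroma must be non-negative", call. = FALSE)
  1 + params$beta * (C_gt / params$chroma_norm)^params$gamma
}

as_lab_matrix <- function(x, what) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 3L) stop(what, " must have 3 channels", call. = FALSE)
    matrix(x, ncol = 3L)
  } else {
    as_color_matrix(x, what)
  }
}

#' Perceptually balanced color loss
#'
#' See [pbc_params()] for the formula. Each of the three terms is averaged
#' independently over all pixels of the batch. The loss is zero if and only
#' if the prediction equals the ground truth.
#'
#' @param pred,gt Predicted and ground-truth Lab values: N x 3 matrices or
#'   H x W x 3 arrays of identical shape.
#' @param params A [pbc_params()] object.
#' @return Scalar loss with attribute `"terms"` holding the three weighted
#'   terms.
#' @export
pbc_loss <- function(pred, gt, params = pbc_params()) {
  if (!identical(dim(pred), dim(gt))) {
    stop("pred and gt must have identical shape", call. = FALSE)
  }
  p <- as_lab_matrix(pred, "pred")
  g <- as_lab_matrix(gt, "gt")
  w <- chroma_weight(chroma(g), params)
  t1 <- params$lambda1 * mean(ciede2000(p, g))
  t2 <- params$lambda2 * mean(w * ((p[, 2] - g[, 2])^2 + (p[, 3] - g[, 3])^2))
  t3 <- params$lambda3 * mean((p[, 1] - g[, 1])^2)
  structure(t1 + t2 + t3, terms = c(dE00 = t1, chromatic = t2, lightness = t3))
}

#' Configure the reflectance network
#'
#' @param input_size Expected square image side in pixels.
#' @param pool_size Side of the average-pooled grid fed to the context
#'   encoder.
#' @param encoder_widths Hidden and code widths of the encoder MLP
#'   (length 2).
#' @param decoder_widths Hidden widths of the per-pixel decoder MLP
#'   (length 2).
#' @param trainable `"all"` or `"decoder_only"` (the frozen-encoder
#'   fine-tuning contract).
#' @param seed Integer seed for deterministic initialization.
#' @return Object of class `reflectance_net_config`.
#' @export
reflectance_net_config <- function(input_size = 64, pool_size = 8,
                                   encoder_widths = c(32, 8),
                                   decoder_widths = c(32, 16),
                                   trainable = c("all", "decoder_only"),
                                   seed = 1L) {
  trainable <- match.arg(trainable)
  if (input_size %% pool_size != 0) {
    stop("input_size must be a multiple of pool_size", call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 pool_size = as.integer(pool_size),
                 encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 trainable = trainable, seed = as.integer(seed)),
            class = "reflectance_net_config")
}

xavier <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
         n_in, n_out)
}

#' Build a reflectance network
#'
#' Deterministic initialization under the config seed. The decoder output is
#' affinely mapped to Lab scale (L around 50, a/b around 0) so the network
#' starts near the center of the gamut.
#'
#' @param config A [reflectance_net_config()].
#' @return Object of class `reflectance_net` with a reported parameter
#'   count.
#' @export
build_reflectance_net <- function(config = reflectance_net_config()) {
  stopifnot(inherits(config, "reflectance_net_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n_enc_in <- 3L * config$pool_size^2
  h_e <- config$encoder_widths[1]
  code <- config$encoder_widths[2]
  h1 <- config$decoder_widths[1]
  h2 <- config$decoder_widths[2]
  par <- list(
    enc_W1 = xavier(n_enc_in, h_e), enc_b1 = rep(0, h_e),
    enc_W2 = xavier(h_e, code), enc_b2 = rep(0, code),
    dec_W1 = xavier(3L + code, h1), dec_b1 = rep(0, h1),
    dec_W2 = xavier(h1, h2), dec_b2 = rep(0, h2),
    dec_W3 = xavier(h2, 3L), dec_b3 = rep(0, 3L)
  )
  n_par <- sum(vapply(par, length, integer(1)))
  structure(list(par = par, config = config,
                 out_scale = c(40, 30, 30), out_offset = c(50, 0, 0),
                 n_parameters = n_par),
            class = "reflectance_net")
}

#' @export
print.reflectance_net <- function(x, ...) {
  cat(sprintf("<reflectance_net: %d parameters, code dim %d, trainable = %s>\n",
              x$n_parameters, x$config$encoder_widths[2], x$config$trainable))
  invisible(x)
}

# Average-pool an H x W x 3 image to pool_size x pool_size x 3 and return
# the encoder feature vector (log-pooled values).
encoder_features <- function(image, pool_size) {
  h <- dim(image)[1]
  f <- h %/% pool_size
  pooled <- vapply(1:3, function(k) {
    m <- image[, , k]
    # block mean via row/col aggregation
    rowagg <- rowsum(m, rep(seq_len(pool_size), each = f)) / f
    t(rowsum(t(rowagg), rep(seq_len(pool_size), each = f)) / f)
  }, matrix(0, pool_size, pool_size))
  log(as.vector(pooled) + 1e-3)
}

# Forward pass pieces; keep intermediates for backprop.
encode_forward <- function(par, x) {
  h <- tanh(drop(x %*% par$enc_W1) + par$enc_b1)
  code <- tanh(drop(h %*% par$enc_W2) + par$enc_b2)
  list(x = x, h = h, code = code)
}

decode_forward <- function(par, rgb, code, out_scale, out_offset) {
  n <- nrow(rgb)
  X <- cbind(log(rgb + 1e-3),
             matrix(code, n, length(code), byrow = TRUE))
  H1 <- tanh(sweep(X %*% par$dec_W1, 2, par$dec_b1, "+"))
  H2 <- tanh(sweep(H1 %*% par$dec_W2, 2, par$dec_b2, "+"))
  Y <- sweep(H2 %*% par$dec_W3, 2, par$dec_b3, "+")
  lab <- sweep(sweep(Y, 2, out_scale, "*"), 2, out_offset, "+")
  list(X = X, H1 = H1, H2 = H2, lab = lab)
}

#' Predict a Lab reflectance map for an image
#'
#' Deterministic inference: encodes the global scene context, then decodes
#' every pixel.
#'
#' @param model A `reflectance_net`.
#' @param image H x W x 3 linear RGB array.
#' @return H x W x 3 array of predicted CIELAB reflectance.
#' @export
predict_reflectance <- function(model, image) {
  stopifnot(inherits(model, "reflectance_net"))
  image <- check_image(image)
  enc <- encode_forward(model$par, encoder_features(image, model$config$pool_size))
  rgb <- matrix(image, ncol = 3L)
  dec <- decode_forward(model$par, rgb, enc$code,
                        model$out_scale, model$out_offset)
  array(dec$lab, dim = dim(image))
}

#' @export
predict.reflectance_net <- function(object, newdata, ...) {
  predict_reflectance(object, newdata)
}

# Gradient of the PBC loss with respect to the predicted Lab matrix.
# Squared-error terms are analytic; the CIEDE2000 term uses forward finite
# differences (one vectorized evaluation per channel).
pbc_loss_grad <- function(pred, gt, params, fd_step = 1e-3) {
  n <- nrow(pred)
  w <- chroma_weight(chroma(gt), params)
  g <- matrix(0, n, 3)
  g[, 1] <- params$lambda3 * 2 * (pred[, 1] - gt[, 1]) / n
  g[, 2] <- params$lambda2 * 2 * w * (pred[, 2] - gt[, 2]) / n
  g[, 3] <- params$lambda2 * 2 * w * (pred[, 3] - gt[, 3]) / n
  if (params$lambda1 > 0) {
    de0 <- ciede2000(pred, gt)
    for (k in 1:3) {
      shifted <- pred
      shifted[, k] <- shifted[, k] + fd_step
      g[, k] <- g[, k] +
        params$lambda1 * (ciede2000(shifted, gt) - de0) / fd_step / n
    }
  }
  g
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0)) {
  state$t <- state$t + 1L
  for (nm in names(grad)) {
    if (nm %in% skip || is.null(grad[[nm]])) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train a reflectance network
#'
#' Minimizes the perceptually balanced color loss over (image, Lab
#' reflectance) pairs by mini-batch Adam. Each step draws a batch of images,
#' encodes each image's scene code, samples a subset of pixels per image and
#' backpropagates through decoder and (unless frozen) encoder. With
#' `trainable = "decoder_only"` in the model config, every encoder parameter
#' is left bit-identical - the frozen-encoder fine-tuning contract.
#'
#' @param model A `reflectance_net`.
#' @param dataset List of training cases; each a list with `rgb`
#'   (H x W x 3 linear RGB) and `lab` (H x W x 3 ground-truth Lab
#'   reflectance).
#' @param params A [pbc_params()] object.
#' @param epochs Number of passes over the dataset.
#' @param lr Adam learning rate.
#' @param batch_images Images per mini-batch.
#' @param pixels_per_image Pixels sampled per image per step.
#' @param seed Integer seed for batching and pixel sampling.
#' @param verbose Print the epoch loss.
#' @return The trained model, with a `loss_trace` element (mean mini-batch
#'   loss per epoch).
#' @export
train_reflectance_net <- function(model, dataset, params = pbc_params(),
                                  epochs = 30, lr = 3e-3, batch_images = 8,
                                  pixels_per_image = 256, seed = 1L,
                                  verbose = FALSE) {
  stopifnot(inherits(model, "reflectance_net"), length(dataset) >= 1)
  par <- model$par
  cfg <- model$config
  freeze <- if (cfg$trainable == "decoder_only") {
    c("enc_W1", "enc_b1", "enc_W2", "enc_b2")
  } else character(0)
  state <- adam_init(par)
  feats <- lapply(dataset, function(d) encoder_features(d$rgb, cfg$pool_size))
  rgbs <- lapply(dataset, function(d) matrix(d$rgb, ncol = 3L))
  labs <- lapply(dataset, function(d) matrix(d$lab, ncol = 3L))
  n_img <- length(dataset)
  trace <- numeric(epochs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_img)
    losses <- c()
    for (start in seq(1, n_img, by = batch_images)) {
      ids <- ord[start:min(start + batch_images - 1, n_img)]
      encs <- lapply(ids, function(i) encode_forward(par, feats[[i]]))
      pix <- lapply(seq_along(ids), function(j) {
        i <- ids[j]
        sel <- sample.int(nrow(rgbs[[i]]), min(pixels_per_image, nrow(rgbs[[i]])))
        list(rgb = rgbs[[i]][sel, , drop = FALSE],
             lab = labs[[i]][sel, , drop = FALSE], img = j)
      })
      rgb_all <- do.call(rbind, lapply(pix, `[[`, "rgb"))
      gt_all <- do.call(rbind, lapply(pix, `[[`, "lab"))
      code_dim <- length(encs[[1]]$code)
      code_rows <- do.call(rbind, lapply(pix, function(p) {
        matrix(encs[[p$img]]$code, nrow(p$rgb), code_dim, byrow = TRUE)
      }))
      img_of_row <- rep(seq_along(ids), vapply(pix, function(p) nrow(p$rgb),
                                               integer(1)))

      n <- nrow(rgb_all)
      X <- cbind(log(rgb_all + 1e-3), code_rows)
      H1 <- tanh(sweep(X %*% par$dec_W1, 2, par$dec_b1, "+"))
      H2 <- tanh(sweep(H1 %*% par$dec_W2, 2, par$dec_b2, "+"))
      Y <- sweep(H2 %*% par$dec_W3, 2, par$dec_b3, "+")
      pred <- sweep(sweep(Y, 2, model$out_scale, "*"), 2, model$out_offset, "+")

      loss <- pbc_loss(pred, gt_all, params)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      }
      losses <- c(losses, as.numeric(loss))

      dpred <- pbc_loss_grad(pred, gt_all, params)
      dY <- sweep(dpred, 2, model$out_scale, "*")
      grad <- list()
      grad$dec_W3 <- t(H2) %*% dY
      grad$dec_b3 <- colSums(dY)
      dH2 <- (dY %*% t(par$dec_W3)) * (1 - H2^2)
      grad$dec_W2 <- t(H1) %*% dH2
      grad$dec_b2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(par$dec_W2)) * (1 - H1^2)
      grad$dec_W1 <- t(X) %*% dH1
      grad$dec_b1 <- colSums(dH1)

      if (!length(freeze)) {
        dX <- dH1 %*% t(par$dec_W1)
        dcode_rows <- dX[, 4:(3 + code_dim), drop = FALSE]
        grad$enc_W1 <- par$enc_W1 * 0
        grad$enc_b1 <- par$enc_b1 * 0
        grad$enc_W2 <- par$enc_W2 * 0
        grad$enc_b2 <- par$enc_b2 * 0
        dcode_img <- rowsum(dcode_rows, img_of_row)
        for (j in seq_along(ids)) {
          e <- encs[[j]]
          dcode <- dcode_img[j, ] * (1 - e$code^2)
          grad$enc_W2 <- grad$enc_W2 + outer(e$h, dcode)
          grad$enc_b2 <- grad$enc_b2 + dcode
          dh <- drop(par$enc_W2 %*% dcode) * (1 - e$h^2)
          grad$enc_W1 <- grad$enc_W1 + outer(e$x, dh)
          grad$enc_b1 <- grad$enc_b1 + dh
        }
      }

      upd <- adam_step(par, grad, state, lr, skip = freeze)
      par <- upd$par
      state <- upd$state
    }
    trace[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d  loss %.4f", ep, trace[ep]))
  }
  model$par <- par
  model$loss_trace <- trace
  model
}

#' Generate a baseline training set for the reflectance network
#'
#' Renders baseline-condition scenes (all cues available) under every
#' illuminant of the set, across seeded layout variations and randomized
#' achromatic-to-colored target reflectances, and pairs each rendered image
#' with its ground-truth reflectance in CIELAB (reflectance lit by the
#' neutral illuminant - the canonical surface color).
#'
#' @param illum_set Output of [make_illuminant_set()].
#' @param n_layouts Layout variations per palette.
#' @param palettes Scene palettes to draw from.
#' @param size Image side in pixels.
#' @param seed Master seed.
#' @return List of training cases, each with `rgb` and `lab` arrays.
#' @export
make_training_set <- function(illum_set, n_layouts = 20,
                              palettes = c("indoor", "outdoor"),
                              size = 64L, seed = 1L) {
  neutral <- illum_set$neutral
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cases <- list()
  i <- 0L
  for (pal in palettes) {
    for (ly in seq_len(n_layouts)) {
      tgt <- stats::runif(1, 0.2, 0.6) *
        (1 + stats::runif(3, -0.35, 0.35) * stats::rbinom(1, 1, 0.5))
      spec <- scene_spec(size = size, palette = pal,
                         target_reflectance = pmin(tgt, 0.62),
                         location = sample.int(3L, 1), seed = seed + 31L * ly)
      for (il in illum_set) {
        i <- i + 1L
        sc <- render_scene(spec, il, neutral)
        refl_lit <- sc$reflectance
        for (k in 1:3) refl_lit[, , k] <- refl_lit[, , k] * neutral$gain[k]
        cases[[i]] <- list(
          rgb = sc$rgb,
          lab = array(linear_rgb_to_lab(matrix(refl_lit, ncol = 3)),
                      dim = dim(sc$rgb)))
      }
    }
  }
  cases
}

#' Checksum of the encoder parameters
#'
#' Used to verify the frozen-encoder contract: identical before and after
#' `decoder_only` training.
#'
#' @param model A `reflectance_net`.
#' @return Numeric digest of all encoder parameters.
#' @export
encoder_checksum <- function(model) {
  stopifnot(inherits(model, "reflectance_net"))
  v <- unlist(model$par[c("enc_W1", "enc_b1", "enc_W2", "enc_b2")])
  sum(v * seq_along(v))
}
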