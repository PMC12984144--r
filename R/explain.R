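# Grad-CAM++ heatmaps.
#
# For a chosen spatially resolved layer A (the concatenated attention output
# for attention models, the last convolutional features for baselines) and a
# class score S (the class logit), the channel weights are built from the
# positive partial derivatives with the closed-form second/third-derivative
# ratios that follow from using exp(S) as the class score:
#   g      = dS/dA
#   alpha  = g^2 / (2 g^2 + sum_{ij} A_ij * g^3)   (per location and channel)
#   w_k    = sum_{ij} alpha_ijk * relu(g_ijk)
#   cam    = relu(sum_k w_k A_k)
# followed by bilinear upsampling to the input size and min-max
# normalization to [0, 1].

#' Grad-CAM++ map from cached activations and gradients
#'
#' The core weighting scheme, exposed separately so toy models with
#' analytically known gradients can be checked directly.
#'
#' @param activations `(H, W, K)` activations of the target layer.
#' @param gradients `(H, W, K)` gradient of the class logit w.r.t. the
#'   activations.
#' @param out_h,out_w spatial size of the returned heatmap.
#' @return `(out_h, out_w)` matrix in `[0, 1]` (identically zero, with a
#'   warning, when the gradient is zero everywhere).
#' @export
gradcam_from_grads <- function(activations, gradients, out_h, out_w) {
  stopifnot(identical(dim(activations), dim(gradients)))
  d <- dim(activations)
  g <- gradients
  g2 <- g * g
  g3 <- g2 * g
  sumA <- apply(activations, 3L, sum)
  denom <- 2 * g2 + sweep(g3, 3L, sumA, `*`)
  alpha <- ifelse(abs(denom) < 1e-12, 0, g2 / denom)
  relu_g <- g * (g > 0)
  w <- apply(alpha * relu_g, 3L, sum)                    # per-channel weight
  cam <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) cam <- cam + w[k] * activations[, , k]
  cam <- cam * (cam > 0)
  up <- bilinear_resize(array(cam, c(d[1], d[2], 1L)),
                        as.integer(out_h), as.integer(out_w))[, , 1L]
  rng <- range(up)
  if (rng[2] - rng[1] < 1e-12) {
    if (all(g == 0)) warning("zero gradient everywhere; heatmap is all zero",
                             call. = FALSE)
    return(matrix(0, out_h, out_w))
  }
  (up - rng[1]) / (rng[2] - rng[1])
}

#' Grad-CAM++ heatmap for a fundus model
#'
#' Computes the class-evidence heatmap of an image at the requested layer:
#' `"attention"` (the concatenated channel/spatial attention output; only
#' for attention models) or `"features"` (the backbone's last convolutional
#' activations). Deterministic in evaluation mode.
#'
#' @param model a `fundus_model` (or `fundus_fit`).
#' @param image `(S, S, 3)` array in `[0, 1]`.
#' @param target_layer `"attention"` or `"features"`; defaults to the
#'   attention output when the model has the attention block.
#' @param target_class class whose evidence is mapped: 0 (normal) or
#'   1 (glaucoma).
#' @return a list of class `gradcam_heatmap`: `values` (`(S, S)` matrix in
#'   `[0, 1]`), `target_layer`, `target_class`.
#' @export
gradcam_pp <- function(model, image, target_layer = NULL, target_class = 1L) {
  if (inherits(model, "fundus_fit")) model <- model$model
  stopifnot(inherits(model, "fundus_model"))
  if (is.null(target_layer)) {
    target_layer <- if (is.null(model$attention)) "features" else "attention"
  }
  if (!target_layer %in% c("attention", "features")) {
    stopf("unknown target layer '%s' (use 'attention' or 'features')", target_layer)
  }
  if (target_layer == "attention" && is.null(model$attention)) {
    stopf("model has no attention block; use target_layer = 'features'")
  }
  if (!target_class %in% c(0L, 1L)) stopf("target_class must be 0 or 1")
  d <- dim(image)
  fwd <- model_fw(model, image, train = FALSE, keep = TRUE)
  dlogits <- matrix(0, 1L, 2L)
  dlogits[1L, target_class + 1L] <- 1
  bwd <- model_bw(model, fwd, dlogits)
  if (target_layer == "attention") {
    A <- fwd$attention_out
    G <- bwd$d_attention_out
  } else {
    A <- fwd$features
    G <- bwd$d_features
  }
  A3 <- array(A, dim(A)[1:3])
  G3 <- array(G, dim(G)[1:3])
  values <- gradcam_from_grads(A3, G3, d[1], d[2])
  structure(list(values = values, target_layer = target_layer,
                 target_class = as.integer(target_class)),
            class = "gradcam_heatmap")
}

#' Save a heatmap as a colour overlay PNG (plus the raw values as TSV)
#'
#' @param image original `(H, W, 3)` image in `[0, 1]`.
#' @param heatmap a [gradcam_pp()] result or a `[0, 1]` matrix of matching
#'   spatial size.
#' @param path output PNG path; the raw heatmap matrix is written next to it
#'   with extension `.tsv`.
#' @param alpha blending weight of the colour map.
#' @return `path`, invisibly.
#' @export
save_heatmap_overlay <- function(image, heatmap, path, alpha = 0.5) {
  hm <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$values else heatmap
  ramp <- grDevices::colorRamp(c("#000080", "#00a0a0", "#ffff00", "#ff2000"))
  cols <- ramp(as.numeric(hm)) / 255
  over <- image
  for (ch in 1:3) {
    over[, , ch] <- (1 - alpha * hm) * image[, , ch] +
      alpha * hm * matrix(cols[, ch], nrow(hm), ncol(hm))
  }
  png::writePNG(clamp01(over), path)
  utils::write.table(hm, paste0(tools::file_path_sans_ext(path), ".tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(path)
}
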