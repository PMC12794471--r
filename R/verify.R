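# Equivariance verification harness: layer-level and model-level checks of
# the roto-translation contracts, plus deliberately broken layer variants
# that the checks must catch.  Failures are report rows, not exceptions.

randn <- function(...) array(rnorm(prod(c(...))), c(...))

# Inject a broken layer variant into a built model, and randomize the
# normalization parameters/statistics (a freshly initialized network passes
# some checks trivially because identity affine parameters hide the defect;
# randomized ones emulate a trained network).
apply_variant <- function(model, variant) {
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    if (ly$type == "gconv" && variant == "no_orientation_shift") {
      ly$orientation_shift <- FALSE
    }
    if (ly$type == "bn") {
      if (variant == "per_orientation_bn" && !is.null(ly$O)) {
        ly$per_orientation <- TRUE
        n <- ly$O * ly$C
        ly$params <- list(gamma = runif(n, 0.5, 1.5), beta = rnorm(n, sd = 0.3))
        ly$state <- list(running_mean = rnorm(n, sd = 0.3),
                         running_var = runif(n, 0.5, 1.5))
      } else {
        n <- length(ly$params$gamma)
        ly$params <- list(gamma = runif(n, 0.5, 1.5), beta = rnorm(n, sd = 0.3))
        ly$state <- list(running_mean = rnorm(n, sd = 0.3),
                         running_var = runif(n, 0.5, 1.5))
      }
    }
    if (ly$type == "se" && variant == "spatial_se") {
      ly$flat <- TRUE
      C <- ly$O * ly$C
      Ch <- max(1L, ceiling(C / ly$r))
      ly$params <- list(w1 = randn(C, Ch), b1 = rnorm(Ch, sd = 0.2),
                        w2 = randn(Ch, C), b2 = rnorm(C, sd = 0.2))
    }
    model$layers[[nm]] <- ly
  }
  model
}

maxabs <- function(a, b) max(abs(a - b))

#' Verify the equivariance contracts of the layer zoo and reference models
#'
#' Runs seeded layer-level checks (lifting and group-convolution
#' equivariance under roto-translations, deconvolution adjointness,
#' batch-norm and squeeze-excitation commutation with group actions) and a
#' model-level invariance check (eval-mode classifier probabilities under
#' the four 90-degree rotations).  Each check reports its maximum deviation;
#' failures are rows with `pass = FALSE`, never exceptions.
#'
#' `variant` injects one of three deliberately broken implementations
#' (`"no_orientation_shift"`, `"per_orientation_bn"`, `"spatial_se"`) whose
#' detection demonstrates that the checks are sensitive to the design
#' decisions that matter.
#'
#' @param config a [model_config()]; orientation counts divisible by 4 give
#'   exact quarter-turn actions.
#' @param tolerance maximum deviation accepted for the exact checks.
#' @param variant `"none"` or one of the broken variants above.
#' @param seed RNG seed for inputs and kernels.
#' @return a data.frame with columns `check`, `max_deviation`, `tolerance`,
#'   `pass`, carrying the variant as an attribute.
#' @export
verify_equivariance <- function(config = model_config(task = "cls",
                                                      n_orientations = 4L,
                                                      extent = 32L,
                                                      stem_filters = 4L,
                                                      lifting_filters = 6L,
                                                      block_channels = c(6L, 8L),
                                                      se_ratio = 4L,
                                                      n_classes = 3L,
                                                      seed = 7L),
                                tolerance = 1e-4,
                                variant = c("none", "no_orientation_shift",
                                            "per_orientation_bn", "spatial_se"),
                                seed = 1L) {
  variant <- match.arg(variant)
  O <- config$n_orientations
  exact <- (O %% 4L) == 0L
  r <- if (exact) O %/% 4L else 1L
  interp_tol <- 5e-2
  set.seed(seed)
  rows <- list()
  add <- function(check, dev, tol) {
    rows[[length(rows) + 1]] <<- data.frame(check = check, max_deviation = dev,
                                            tolerance = tol, pass = dev <= tol)
  }

  # inputs supported away from the border so roto-translations move no
  # content across the zero-padding boundary
  img <- circular_mask(randn(16, 16), 0.6)
  tr <- c(2, -1)

  # --- lifting equivariance
  kern <- spatial_kernel(randn(3, 3, 1, 2))
  g <- se2_element(r, tr, O)
  lhs <- lifting_conv(act_on_image(g, img), kern, O)
  rhs <- act_on_feature_map(lifting_conv(img, kern, O), r, tr)
  add("lifting_equivariance", maxabs(lhs, rhs), if (exact) tolerance else interp_tol)

  # --- group convolution equivariance
  f <- array(0, c(16, 16, O, 2))
  for (m in seq_len(O)) for (c in 1:2) f[, , m, c] <- circular_mask(randn(16, 16), 0.6)
  gk_w <- randn(3, 3, O, 2, 3)
  gk <- group_kernel(gk_w)
  lhs <- group_conv(act_on_feature_map(f, r, tr), gk,
                    orientation_shift = variant != "no_orientation_shift")
  rhs <- act_on_feature_map(group_conv(f, gk,
                                       orientation_shift = variant != "no_orientation_shift"),
                            r, tr)
  add("groupconv_equivariance", maxabs(lhs, rhs), if (exact) tolerance else interp_tol)

  # --- deconvolution adjointness: <group_conv(f), h> == <f, group_deconv(h)>
  devs <- vapply(1:5, function(i) {
    ff <- randn(8, 8, O, 2)
    kk <- group_kernel(randn(3, 3, O, 2, 3))
    hh <- randn(4, 4, O, 3)
    cf <- group_conv(ff, kk, stride = 2L)
    dc <- group_deconv(hh, kk, stride = 2L)
    ip1 <- sum(cf * hh); ip2 <- sum(ff * dc)
    abs(ip1 - ip2) / max(abs(ip1), 1e-12)
  }, 0)
  add("deconv_adjointness", max(devs), tolerance)

  # --- batch norm commutation with the group action (trained-like params).
  # Rotation-only actions here: rotations by quarter turns permute the grid
  # bijectively, whereas translations expose zero-filled pixels that an
  # affine normalization maps away from zero (a boundary artifact, not a
  # property of the layer).
  bn <- init_layer("bn", C = 2L, O = O)
  bn <- apply_variant(list(layers = list(bn = bn)), variant)$layers$bn
  xb <- array(f, c(dim(f), 1L))
  for (mode_train in c(TRUE, FALSE)) {
    lhs <- layer_forward(bn, array(act_on_feature_map(f, r), c(dim(f), 1L)),
                         training = mode_train)$out
    rhs0 <- layer_forward(bn, xb, training = mode_train)$out
    rhs <- array(act_on_feature_map(array(rhs0, dim(f)), r), c(dim(f), 1L))
    add(paste0("bn_commutes_", if (mode_train) "train" else "eval"),
        maxabs(lhs, rhs), if (exact) tolerance else interp_tol)
  }

  # --- squeeze-excitation commutation (rotation-only, as above)
  se <- init_layer("se", C = 2L, O = O, r = 2L)
  se <- apply_variant(list(layers = list(se = se)), variant)$layers$se
  lhs <- layer_forward(se, array(act_on_feature_map(f, r), c(dim(f), 1L)))$out
  rhs0 <- layer_forward(se, xb)$out
  rhs <- array(act_on_feature_map(array(rhs0, dim(f)), r), c(dim(f), 1L))
  add("se_commutes", maxabs(lhs, rhs), if (exact) tolerance else interp_tol)

  # --- orientation projection invariance under orientation shifts
  add("projection_shift_invariance",
      maxabs(orientation_project(shift_orientation(f, 1L)), orientation_project(f)),
      tolerance)

  # --- end-to-end classifier invariance (eval mode, masked input)
  model <- build_classifier(config)
  model <- apply_variant(model, variant)
  timg <- circular_mask(matrix(runif(config$extent^2), config$extent), 0.9)
  probs <- vapply(0:3, function(q) {
    gq <- se2_element((q * (O %/% 4)) %% O, c(0, 0), O)
    ximg <- if (exact) act_on_image(gq, timg) else timg
    predict_model(model, ximg)[, 1]
  }, numeric(config$n_classes))
  dev <- max(apply(probs, 1, function(v) diff(range(v))))
  add("endtoend_invariance", dev, if (exact) 1e-3 else interp_tol)

  out <- do.call(rbind, rows)
  attr(out, "variant") <- variant
  out
}
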