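# The five inverse-imaging architectures.
#
# Shared geometry: volumes are L^3 with L divisible by 4; the encoder halves
# the side twice (conv 3^3 -> ReLU -> maxpool, channels 32 then 64) and a
# final 1^3 single-channel convolution leaves a spatial latent code of side
# L/4. The decoder mirrors it (channels 64 then 32, nearest-neighbour
# upsampling) and ends in a bounded ReLU so reconstructions stay in [0, 1].
# Mappers turn the m-muscle MEP vector into the decoder's latent input;
# variational paths emit a diagonal-Gaussian (mu, logvar) and sample z by
# reparameterization, followed by a fully connected "sampler output" layer
# that restores the spatial code.

#' Model variants
#'
#' The five architecture/training-regime combinations: `"ae_decoder"` (a),
#' `"direct_conv"` (b), `"vae_decoder"` (c), `"vae_sampler_decoder"` (d) and
#' `"direct_variational"` (e). Variants a, c, d train in two stages (E-field
#' autoencoding, then MEP-to-latent mapping against the frozen decoder);
#' b and e train the whole reverse path in a single stage.
#'
#' @param variant letter `"a"`..`"e"` or full name.
#' @return Canonical variant name.
#' @export
model_variant <- function(variant) {
  full <- c(a = "ae_decoder", b = "direct_conv", c = "vae_decoder",
            d = "vae_sampler_decoder", e = "direct_variational")
  v <- tolower(as.character(variant))
  if (v %in% names(full)) return(unname(full[v]))
  if (v %in% full) return(v)
  stop_mf("unknown model variant '%s' (use a-e or %s)", variant,
          paste(full, collapse = ", "))
}

variant_letter <- function(variant)
  c(ae_decoder = "a", direct_conv = "b", vae_decoder = "c",
    vae_sampler_decoder = "d", direct_variational = "e")[[variant]]

two_stage_variants <- c("ae_decoder", "vae_decoder", "vae_sampler_decoder")

#' Build the E-field encoder
#'
#' Two convolution-ReLU-maxpool blocks (32 then 64 channels, 3x3x3 kernels,
#' padding 1) followed by a single-channel 1x1x1 convolution and ReLU,
#' compressing an L^3 volume to an (L/4)^3 spatial code. The variational form
#' adds a flattening layer and linear (mu, logvar) heads of width
#' `latent_dim` (the heads are linear so logvar can go negative).
#'
#' @param input_side cube side L, divisible by 4.
#' @param variational logical; emit a (mu, logvar) pair instead of a
#'   deterministic code.
#' @param latent_dim length n of the latent vector (variational only).
#' @param channels the two hidden channel counts.
#' @return An encoder component.
#' @export
build_encoder <- function(input_side, variational = FALSE, latent_dim = 64L,
                          channels = c(32L, 64L)) {
  if (input_side %% 4L != 0L)
    stop_mf("input side must be divisible by 4, got %d", input_side)
  conv <- list(nn_conv3d(1L, channels[1], 3L), nn_relu(), nn_maxpool(),
               nn_conv3d(channels[1], channels[2], 3L), nn_relu(), nn_maxpool(),
               nn_conv3d(channels[2], 1L, 1L), nn_relu())
  code_size <- (input_side %/% 4L)^3
  if (!variational)
    return(list(kind = "det", conv = conv, code_size = code_size))
  fc_logvar <- nn_fc(code_size, latent_dim)
  fc_logvar$params$b[] <- -4 # posterior starts tight: z ~ mu at init
  list(kind = "var", conv = conv, code_size = code_size,
       flatten = nn_flatten(),
       fc_mu = nn_fc(code_size, latent_dim),
       fc_logvar = fc_logvar)
}

#' Build the E-field decoder
#'
#' Two convolution-ReLU-upsample blocks (64 then 32 channels) followed by a
#' single-channel 1x1x1 convolution and a bounded ReLU, expanding an (L/4)^3
#' code back to the L^3 volume with all outputs in \[0, 1\].
#'
#' @param code_side side of the spatial latent code (L/4).
#' @param channels the two hidden channel counts.
#' @return A decoder component.
#' @export
build_decoder <- function(code_side, channels = c(64L, 32L)) {
  list(kind = "decoder", out_side = 4L * code_side,
       layers = list(nn_conv3d(1L, channels[1], 3L), nn_relu(), nn_upsample(),
                     nn_conv3d(channels[1], channels[2], 3L), nn_relu(),
                     nn_upsample(),
                     nn_conv3d(channels[2], 1L, 1L), nn_brelu()))
}

#' Build the variational sampling head
#'
#' The reparameterization draw plus the fully connected layer (with ReLU and
#' reshape) that maps a sampled z back to the decoder's spatial code. In the
#' VAE-Sampler-Decoder variant this component is learned on the autoencoding
#' path and reloaded (and retrained) on the MEP path.
#'
#' @param latent_dim latent length n.
#' @param code_size flattened spatial code size (L/4)^3.
#' @return A sampler component.
#' @export
build_sampler <- function(latent_dim, code_size) {
  list(kind = "sampler",
       reparam = new_layer("reparam"),
       out = list(nn_fc(latent_dim, code_size), nn_relu(), nn_unflatten()))
}

#' Build the MEP-to-latent mapper
#'
#' All mappers start from the length-m MEP vector with a fully connected
#' stack (m -> 256 -> ...). The purely convolutional variants (a, b) reshape
#' to an (L/2)^3 volume and pass a convolution + batch-norm + ReLU + maxpool
#' block plus a 1x1x1 convolution (batch norm is used only in these two
#' variants). Variant (c) is fully connected straight to the spatial code.
#' The variational mappers (d, e) end in linear (mu, logvar) heads feeding
#' the sampler.
#'
#' @param variant model variant (letter or name).
#' @param m MEP vector length.
#' @param code_side side of the spatial code (L/4).
#' @param latent_dim latent length for the variational heads.
#' @param hidden width of the first fully connected layer.
#' @return A mapper component.
#' @export
build_mapper <- function(variant, m, code_side, latent_dim = 64L,
                         hidden = 256L) {
  stopifnot(m >= 1)
  variant <- model_variant(variant)
  code_size <- code_side^3
  if (variant %in% c("ae_decoder", "direct_conv")) {
    half <- (2L * code_side)^3
    list(kind = "conv",
         layers = list(nn_fc(m, hidden), nn_relu(),
                       nn_fc(hidden, half), nn_relu(), nn_unflatten(),
                       nn_conv3d(1L, 8L, 3L), nn_batchnorm(8L), nn_relu(),
                       nn_maxpool(),
                       nn_conv3d(8L, 1L, 1L), nn_batchnorm(1L), nn_relu()))
  } else if (variant == "vae_decoder") {
    list(kind = "fc",
         layers = list(nn_fc(m, hidden), nn_relu(),
                       nn_fc(hidden, code_size), nn_relu(), nn_unflatten()))
  } else {
    fc_logvar <- nn_fc(hidden, latent_dim)
    fc_logvar$params$b[] <- -4 # posterior starts tight: z ~ mu at init
    list(kind = "var",
         trunk = list(nn_fc(m, hidden), nn_relu()),
         fc_mu = nn_fc(hidden, latent_dim),
         fc_logvar = fc_logvar)
  }
}

#' Assemble one model variant
#'
#' Wires encoder, sampler, mapper and decoder according to the variant:
#' two-stage variants (a, c, d) get the autoencoding components plus the
#' mapper; single-stage variants (b, e) get only the mapper(+sampler) and
#' decoder. Records which components freeze after which stage. Weights are
#' Glorot-uniform, seeded.
#'
#' @param variant letter `"a"`..`"e"` or full name.
#' @param input_side volume side L (divisible by 4).
#' @param m MEP vector length.
#' @param latent_dim latent length n for variational paths.
#' @param seed integer seed for weight initialization.
#' @return An object of class `network_bundle`.
#' @export
assemble_model <- function(variant, input_side, m = 15L, latent_dim = 64L,
                           seed = 1L) {
  variant <- model_variant(variant)
  if (input_side %% 4L != 0L)
    stop_mf("input side must be divisible by 4, got %d", input_side)
  code_side <- input_side %/% 4L
  with_seed(seed, {
    comps <- list()
    if (variant == "ae_decoder")
      comps$encoder <- build_encoder(input_side, FALSE, latent_dim)
    if (variant %in% c("vae_decoder", "vae_sampler_decoder"))
      comps$encoder <- build_encoder(input_side, TRUE, latent_dim)
    if (variant %in% c("vae_decoder", "vae_sampler_decoder",
                       "direct_variational"))
      comps$sampler <- build_sampler(latent_dim, code_side^3)
    comps$decoder <- build_decoder(code_side)
    comps$mapper <- build_mapper(variant, m, code_side, latent_dim)
    structure(list(variant = variant, input_side = as.integer(input_side),
                   m = as.integer(m), latent_dim = as.integer(latent_dim),
                   code_side = code_side, components = comps,
                   frozen = character(0), trained = character(0),
                   init_seed = as.integer(seed)),
              class = "network_bundle")
  })
}

#' @export
print.network_bundle <- function(x, ...) {
  cat(sprintf("<network_bundle> %s (%s): %d^3 volume, m=%d, latent n=%d\n",
              x$variant, variant_letter(x$variant), x$input_side, x$m,
              x$latent_dim))
  for (nm in names(x$components))
    cat(sprintf("  %-8s %8d parameters%s\n", nm,
                component_param_count(x$components[[nm]]),
                if (nm %in% x$frozen) " [frozen]" else ""))
  invisible(x)
}

# --- component plumbing ---------------------------------------------------

component_layers <- function(comp) {
  if (is.null(comp)) return(list())
  out <- list()
  for (f in c("conv", "layers", "trunk", "out"))
    if (!is.null(comp[[f]])) out <- c(out, comp[[f]])
  for (f in c("fc_mu", "fc_logvar"))
    if (!is.null(comp[[f]])) out <- c(out, list(comp[[f]]))
  out
}

component_param_count <- function(comp) layer_param_count(component_layers(comp))

#' Parameter checksum of a model component
#'
#' Deterministic fingerprint (sum, sum of squares, count over all weights)
#' used to audit the freeze contracts: a frozen component's checksum must be
#' identical across training steps.
#'
#' @param bundle a `network_bundle`.
#' @param component component name (`"encoder"`, `"sampler"`, `"mapper"`,
#'   `"decoder"`).
#' @return Named numeric vector `(sum, sumsq, n)`.
#' @export
component_checksum <- function(bundle, component) {
  stopifnot(inherits(bundle, "network_bundle"))
  comp <- bundle$components[[component]]
  if (is.null(comp)) stop_mf("bundle has no component '%s'", component)
  layers_checksum(component_layers(comp))
}

# reparameterization with cached noise for the backward pass
reparam_forward <- function(st, mu, logvar, sampling = TRUE) {
  eps <- if (sampling) matrix(stats::rnorm(length(mu)), nrow(mu)) else
    matrix(0, nrow(mu), ncol(mu))
  st$cache <- list(eps = eps, half = exp(0.5 * logvar))
  mu + st$cache$half * eps
}

reparam_backward <- function(st, dz) {
  list(dmu = dz, dlogvar = 0.5 * dz * st$cache$eps * st$cache$half)
}

# --- full network passes --------------------------------------------------

# Autoencoding (forward-stage) pass: X -> code/(mu,logvar) -> [z ->] X-hat.
# Only defined for the two-stage variants.
net_forward_autoenc <- function(bundle, x, B, training = TRUE, sampling = TRUE) {
  enc <- bundle$components$encoder
  if (is.null(enc)) stop_mf("variant '%s' has no autoencoding path", bundle$variant)
  h <- chain_forward(enc$conv, x, B, training)
  if (enc$kind == "det") {
    pred <- chain_forward(bundle$components$decoder$layers, h, B, training)
    return(list(pred = pred, mu = NULL, logvar = NULL))
  }
  flat <- nn_forward(enc$flatten, h, B, training)
  mu <- nn_forward(enc$fc_mu, flat, B, training)
  logvar <- nn_forward(enc$fc_logvar, flat, B, training)
  smp <- bundle$components$sampler
  z <- reparam_forward(smp$reparam, mu, logvar, sampling)
  code <- chain_forward(smp$out, z, B, training)
  pred <- chain_forward(bundle$components$decoder$layers, code, B, training)
  list(pred = pred, mu = mu, logvar = logvar)
}

net_backward_autoenc <- function(bundle, dpred, dmu, dlogvar, B) {
  enc <- bundle$components$encoder
  dcode <- chain_backward(bundle$components$decoder$layers, dpred, B)
  if (enc$kind == "det") {
    chain_backward(enc$conv, dcode, B)
    return(invisible(NULL))
  }
  smp <- bundle$components$sampler
  dz <- chain_backward(smp$out, dcode, B)
  rp <- reparam_backward(smp$reparam, dz)
  dmu_t <- rp$dmu + (dmu %||% 0)
  dlv_t <- rp$dlogvar + (dlogvar %||% 0)
  dflat <- nn_backward(enc$fc_mu, dmu_t, B) + nn_backward(enc$fc_logvar, dlv_t, B)
  dh <- nn_backward(enc$flatten, dflat, B)
  chain_backward(enc$conv, dh, B)
  invisible(NULL)
}

# Reverse (inference) pass: y -> latent code -> X-hat.
net_forward_reverse <- function(bundle, y, B, training = TRUE, sampling = TRUE) {
  map <- bundle$components$mapper
  if (map$kind %in% c("conv", "fc")) {
    code <- chain_forward(map$layers, y, B, training)
    pred <- chain_forward(bundle$components$decoder$layers, code, B, training)
    return(list(pred = pred, mu = NULL, logvar = NULL))
  }
  h <- chain_forward(map$trunk, y, B, training)
  mu <- nn_forward(map$fc_mu, h, B, training)
  logvar <- nn_forward(map$fc_logvar, h, B, training)
  smp <- bundle$components$sampler
  z <- reparam_forward(smp$reparam, mu, logvar, sampling)
  code <- chain_forward(smp$out, z, B, training)
  pred <- chain_forward(bundle$components$decoder$layers, code, B, training)
  list(pred = pred, mu = mu, logvar = logvar)
}

net_backward_reverse <- function(bundle, dpred, dmu, dlogvar, B) {
  map <- bundle$components$mapper
  dcode <- chain_backward(bundle$components$decoder$layers, dpred, B)
  if (map$kind %in% c("conv", "fc")) {
    chain_backward(map$layers, dcode, B)
    return(invisible(NULL))
  }
  smp <- bundle$components$sampler
  dz <- chain_backward(smp$out, dcode, B)
  rp <- reparam_backward(smp$reparam, dz)
  dmu_t <- rp$dmu + (dmu %||% 0)
  dlv_t <- rp$dlogvar + (dlogvar %||% 0)
  dh <- nn_backward(map$fc_mu, dmu_t, B) + nn_backward(map$fc_logvar, dlv_t, B)
  chain_backward(map$trunk, dh, B)
  invisible(NULL)
}
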