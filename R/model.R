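# Modified attention U-Net whose encoder doubles as the discriminator.
#
# Encoder: a full-resolution stem followed by five residual downsampling
# stages, each halving H and W (so inputs must be divisible by 32), then two
# further convolutions (d6/d7) that change channels only. The bottleneck is
# pooled to a one-dimensional vector feeding four purely affine heads: a
# latent vector (default 32-d), an auxiliary latent, a single "validity"
# scalar obtained by a fully connected reduction of the latent, auxiliary
# class logits (more nodes than classes, so lesion-free "dummy" images get
# their own class), and a single adversarial logit.
#
# Decoder: five upsampling stages, each doubling H and W. Skip features pass
# through residual units (F(x) + x) and an additive attention gate before
# concatenation. The segmentation output is bounded to [0, 1] by a sigmoid.
#
# During adversarial training the encoder + heads form the discriminator
# (weight-clipped); the skip residual units, attention gates and decoder form
# the generator (never clipped).

#' Model configuration
#'
#' @param latent_dim Dimension of the latent vector head.
#' @param num_lesion_classes Number of color-coded classes (7).
#' @param aux_output_nodes Auxiliary classification nodes; must exceed
#'   `num_lesion_classes` (default 9 = 7 lesions + dummy + spare).
#' @param residual_units_per_skip Residual units on each skip connection.
#' @param encoder_channels 5-tuple of stage widths; the stem uses the first
#'   entry. Decoder widths mirror the encoder.
#' @param latent_aux_dim Dimension of the auxiliary latent (feeds the
#'   adversarial head).
#' @param input_channels Image channels (3).
#' @return An object of class `model_config`.
#' @export
model_config <- function(latent_dim = 32L,
                         num_lesion_classes = 7L,
                         aux_output_nodes = 9L,
                         residual_units_per_skip = 2L,
                         encoder_channels = c(64L, 64L, 128L, 256L, 512L),
                         latent_aux_dim = latent_dim,
                         input_channels = 3L) {
  stopifnot(latent_dim >= 2, aux_output_nodes > num_lesion_classes,
            residual_units_per_skip >= 1, length(encoder_channels) == 5L)
  structure(list(latent_dim = as.integer(latent_dim),
                 num_lesion_classes = as.integer(num_lesion_classes),
                 aux_output_nodes = as.integer(aux_output_nodes),
                 residual_units_per_skip = as.integer(residual_units_per_skip),
                 encoder_channels = as.integer(encoder_channels),
                 latent_aux_dim = as.integer(latent_aux_dim),
                 input_channels = as.integer(input_channels)),
            class = "model_config")
}

conv_init <- function(kh, kw, cin, cout, sd = sqrt(2 / (kh * kw * cin))) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sd), dim = c(kh, kw, cin, cout))
}

#' Build the network
#'
#' Initialises all parameters (He-style for generator convolutions; small
#' Gaussians for the discriminator, whose weights live inside the clipping
#' box during adversarial training).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialisation.
#' @return An object of class `larynet_model`: parameter list, config and
#'   the generator/discriminator parameter grouping.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  e <- config$encoder_channels
  inC <- config$input_channels
  dsd <- 0.005  # discriminator init: inside the default clipping box
  P <- list()
  add_norm <- function(P, nm, ch, gamma = 1) {
    P[[paste0(nm, ".g")]] <- rep(gamma, ch)
    P[[paste0(nm, ".be")]] <- rep(0, ch)
    P
  }
  # ---- encoder (discriminator group) ----
  P[["stem.w"]] <- conv_init(3, 3, inC, e[1], sd = dsd)
  P[["stem.b"]] <- rep(0, e[1])
  P <- add_norm(P, "stem.n", e[1])
  cin <- e[1]
  for (i in 1:5) {
    nm <- paste0("s", i)
    P[[paste0(nm, ".c1.w")]] <- conv_init(3, 3, cin, e[i], sd = dsd)
    P[[paste0(nm, ".c1.b")]] <- rep(0, e[i])
    P <- add_norm(P, paste0(nm, ".n1"), e[i])
    P[[paste0(nm, ".c2.w")]] <- conv_init(3, 3, e[i], e[i], sd = dsd)
    P[[paste0(nm, ".c2.b")]] <- rep(0, e[i])
    P <- add_norm(P, paste0(nm, ".n2"), e[i])
    P[[paste0(nm, ".sc.w")]] <- conv_init(1, 1, cin, e[i], sd = dsd)
    P[[paste0(nm, ".sc.b")]] <- rep(0, e[i])
    P <- add_norm(P, paste0(nm, ".nsc"), e[i])
    cin <- e[i]
  }
  for (nm in c("d6", "d7")) {
    P[[paste0(nm, ".w")]] <- conv_init(3, 3, e[5], e[5], sd = dsd)
    P[[paste0(nm, ".b")]] <- rep(0, e[5])
    P <- add_norm(P, paste0(nm, ".n"), e[5])
  }
  # heads: purely affine (no activation inside); they read the mean+sd
  # pooling of the raw d7 response, hence 2 * e[5] inputs
  P[["l7.W"]] <- matrix(stats::rnorm(config$latent_dim * 2 * e[5], 0, dsd),
                        config$latent_dim, 2 * e[5])
  P[["l7.b"]] <- rep(0, config$latent_dim)
  P[["l8.W"]] <- matrix(stats::rnorm(config$latent_aux_dim * 2 * e[5], 0, dsd),
                        config$latent_aux_dim, 2 * e[5])
  P[["l8.b"]] <- rep(0, config$latent_aux_dim)
  P[["val.W"]] <- matrix(stats::rnorm(config$latent_dim, 0, dsd), 1,
                         config$latent_dim)
  P[["val.b"]] <- 0
  P[["aux.W"]] <- matrix(stats::rnorm(config$aux_output_nodes * config$latent_dim,
                                      0, dsd),
                         config$aux_output_nodes, config$latent_dim)
  P[["aux.b"]] <- rep(0, config$aux_output_nodes)
  P[["adv.W"]] <- matrix(stats::rnorm(config$latent_aux_dim, 0, dsd), 1,
                         config$latent_aux_dim)
  P[["adv.b"]] <- 0
  disc_names <- names(P)
  # ---- decoder (generator group) ----
  f <- c(e[1], e[1], e[2], e[3], e[4])  # decoder width at stage j
  # skip sources: stages 4..1 for decoder stages 5..2; the full-resolution
  # skip of stage 1 is the raw input image, so absolute color survives the
  # normalised encoder path
  s_ch <- c(inC, e[1], e[2], e[3], e[4])
  cin <- e[5]
  for (j in 5:1) {
    nm <- paste0("u", j)
    P[[paste0(nm, ".c1.w")]] <- conv_init(3, 3, cin, f[j])
    P[[paste0(nm, ".c1.b")]] <- rep(0, f[j])
    P <- add_norm(P, paste0(nm, ".n1"), f[j])
    for (k in seq_len(config$residual_units_per_skip)) {
      rn <- paste0(nm, ".r", k)
      P[[paste0(rn, ".c1.w")]] <- conv_init(3, 3, s_ch[j], s_ch[j])
      P[[paste0(rn, ".c1.b")]] <- rep(0, s_ch[j])
      P <- add_norm(P, paste0(rn, ".n1"), s_ch[j])
      P[[paste0(rn, ".c2.w")]] <- conv_init(3, 3, s_ch[j], s_ch[j])
      P[[paste0(rn, ".c2.b")]] <- rep(0, s_ch[j])
      P <- add_norm(P, paste0(rn, ".n2"), s_ch[j])
    }
    att <- max(4L, f[j] %/% 2L)
    P[[paste0(nm, ".att.s.w")]] <- conv_init(1, 1, s_ch[j], att)
    P[[paste0(nm, ".att.s.b")]] <- rep(0, att)
    P[[paste0(nm, ".att.g.w")]] <- conv_init(1, 1, f[j], att)
    P[[paste0(nm, ".att.g.b")]] <- rep(0, att)
    P[[paste0(nm, ".att.p.w")]] <- conv_init(1, 1, att, 1)
    P[[paste0(nm, ".att.p.b")]] <- 0
    P[[paste0(nm, ".c2.w")]] <- conv_init(3, 3, f[j] + s_ch[j], f[j])
    P[[paste0(nm, ".c2.b")]] <- rep(0, f[j])
    P <- add_norm(P, paste0(nm, ".n2"), f[j])
    cin <- f[j]
  }
  # small output-head init: start the bounded segmentation near mid-gray so
  # the sparse lesion pixels keep live gradients instead of saturating black
  P[["out.w"]] <- conv_init(3, 3, f[1], 3, sd = 0.05)
  P[["out.b"]] <- rep(0, 3)
  gen_names <- setdiff(names(P), disc_names)
  structure(list(params = P, config = config,
                 groups = list(discriminator = disc_names,
                               generator = gen_names)),
            class = "larynet_model")
}

#' Total number of trainable parameters
#' @param model A `larynet_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) sum(vapply(model$params, length, integer(1)))

#' @export
print.larynet_model <- function(x, ...) {
  cat("<larynet_model>",
      sprintf("  encoder channels: %s", paste(x$config$encoder_channels,
                                              collapse = ", ")),
      sprintf("  latent dim: %d | aux nodes: %d | skip residual units: %d",
              x$config$latent_dim, x$config$aux_output_nodes,
              x$config$residual_units_per_skip),
      sprintf("  parameters: %d (discriminator %d, generator %d)",
              n_parameters(x),
              sum(vapply(x$params[x$groups$discriminator], length, integer(1))),
              sum(vapply(x$params[x$groups$generator], length, integer(1)))),
      sep = "\n")
  invisible(x)
}

# Wrap every parameter as an autodiff leaf node.
wrap_params <- function(model) lapply(model$params, ag_const)

check_input_dims <- function(image, cfg) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != cfg$input_channels)
    stop("input must be an H x W x ", cfg$input_channels, " array")
  if (any(d[1:2] %% 32 != 0))
    stop("input height and width must be divisible by 32 (got ",
         d[1], " x ", d[2], ")")
  invisible(d)
}

conv_in_relu <- function(x, P, wn, nn, stride = 1L, pad = 1L) {
  ag_relu(ag_instnorm(ag_conv2d(x, P[[paste0(wn, ".w")]],
                                P[[paste0(wn, ".b")]], stride, pad),
                      P[[paste0(nn, ".g")]], P[[paste0(nn, ".be")]]))
}

# One downsampling residual stage (stride-2 main path + projected shortcut).
down_stage <- function(x, P, nm) {
  h <- conv_in_relu(x, P, paste0(nm, ".c1"), paste0(nm, ".n1"), stride = 2L)
  h <- ag_instnorm(ag_conv2d(h, P[[paste0(nm, ".c2.w")]],
                             P[[paste0(nm, ".c2.b")]], 1L, 1L),
                   P[[paste0(nm, ".n2.g")]], P[[paste0(nm, ".n2.be")]])
  s <- ag_instnorm(ag_conv2d(x, P[[paste0(nm, ".sc.w")]],
                             P[[paste0(nm, ".sc.b")]], 2L, 0L),
                   P[[paste0(nm, ".nsc.g")]], P[[paste0(nm, ".nsc.be")]])
  ag_relu(ag_add(h, s))
}

# Residual unit F(x) + x (identity when all its weights are zero, since skip
# inputs are post-ReLU and hence non-negative).
res_unit <- function(x, P, nm) {
  h <- conv_in_relu(x, P, paste0(nm, ".c1"), paste0(nm, ".n1"))
  h <- ag_instnorm(ag_conv2d(h, P[[paste0(nm, ".c2.w")]],
                             P[[paste0(nm, ".c2.b")]], 1L, 1L),
                   P[[paste0(nm, ".n2.g")]], P[[paste0(nm, ".n2.be")]])
  ag_relu(ag_add(h, x))
}

# Encoder graph: skips, pooled bottleneck and the affine heads.
#
# The d6/d7 convolutions change channels only. The decoder consumes the
# normalised bottleneck; the heads pool the *raw* d7 response (channel means
# and standard deviations), because instance normalisation standardises
# away exactly the global statistics the open-set heads need.
encoder_graph <- function(P, x, cfg) {
  skips <- vector("list", 6L)
  skips[[1]] <- x  # raw image as the full-resolution skip
  cur <- conv_in_relu(x, P, "stem", "stem.n")
  for (i in 1:5) {
    cur <- down_stage(cur, P, paste0("s", i))
    skips[[i + 1]] <- cur
  }
  b6 <- conv_in_relu(cur, P, "d6", "d6.n")
  raw7 <- ag_conv2d(b6, P[["d7.w"]], P[["d7.b"]], 1L, 1L)
  bott <- ag_relu(ag_instnorm(raw7, P[["d7.n.g"]], P[["d7.n.be"]]))
  mu <- ag_gap(raw7)
  sdev <- ag_sqrt(ag_add_scalar(ag_sub(ag_gap(ag_square(raw7)),
                                       ag_square(mu)), 1e-8))
  pooled <- ag_concat_v(mu, sdev)
  latent <- ag_dense(pooled, P[["l7.W"]], P[["l7.b"]])
  latent_aux <- ag_dense(pooled, P[["l8.W"]], P[["l8.b"]])
  validity <- ag_dense(latent, P[["val.W"]], P[["val.b"]])
  aux <- ag_dense(latent, P[["aux.W"]], P[["aux.b"]])
  adv <- ag_dense(latent_aux, P[["adv.W"]], P[["adv.b"]])
  list(skips = skips, bottleneck = bott, pooled = pooled, latent = latent,
       latent_aux = latent_aux, validity = validity, aux = aux, adv = adv)
}

# Additive attention gate: the decoder feature g gates the skip feature s.
attention_gate <- function(s, g, P, nm) {
  a <- ag_relu(ag_add(
    ag_conv2d(s, P[[paste0(nm, ".s.w")]], P[[paste0(nm, ".s.b")]], 1L, 0L),
    ag_conv2d(g, P[[paste0(nm, ".g.w")]], P[[paste0(nm, ".g.b")]], 1L, 0L)))
  psi <- ag_sigmoid(ag_conv2d(a, P[[paste0(nm, ".p.w")]],
                              P[[paste0(nm, ".p.b")]], 1L, 0L))
  ag_mul_gate(s, psi)
}

# Decoder graph from encoder skips + bottleneck to the bounded segmentation.
decoder_graph <- function(P, enc, cfg) {
  cur <- enc$bottleneck
  for (j in 5:1) {
    nm <- paste0("u", j)
    g <- conv_in_relu(ag_upsample2(cur), P, paste0(nm, ".c1"), paste0(nm, ".n1"))
    s <- enc$skips[[j]]
    for (k in seq_len(cfg$residual_units_per_skip))
      s <- res_unit(s, P, paste0(nm, ".r", k))
    s <- attention_gate(s, g, P, paste0(nm, ".att"))
    cur <- conv_in_relu(ag_concat_c(g, s), P, paste0(nm, ".c2"), paste0(nm, ".n2"))
  }
  ag_clamp01(ag_conv2d(cur, P[["out.w"]], P[["out.b"]], 1L, 1L))
}

#' Full forward pass
#'
#' Deterministic in inference: identical inputs and weights give identical
#' outputs.
#'
#' @param model A `larynet_model`.
#' @param image `H x W x 3` array in `[0, 1]`, dims divisible by 32.
#' @return A list with `seg_image` (same shape, in `[0, 1]`), `latent`,
#'   `latent_aux`, `validity_logit`, `aux_logits`, `adv_logit` and the
#'   bottleneck `features` used for Gram-matrix scores.
#' @export
model_forward <- function(model, image) {
  check_input_dims(image, model$config)
  P <- wrap_params(model)
  enc <- encoder_graph(P, ag_const(image), model$config)
  seg <- decoder_graph(P, enc, model$config)
  list(seg_image = seg$v,
       latent = enc$latent$v,
       latent_aux = enc$latent_aux$v,
       validity_logit = as.numeric(enc$validity$v),
       aux_logits = enc$aux$v,
       adv_logit = as.numeric(enc$adv$v),
       features = enc$bottleneck$v)
}

#' Encoder-only pass
#'
#' @inheritParams model_forward
#' @return A list with `latent`, `latent_aux`, `validity_logit`,
#'   `aux_logits`, `adv_logit` and bottleneck `features`.
#' @export
model_encode <- function(model, image) {
  check_input_dims(image, model$config)
  P <- wrap_params(model)
  enc <- encoder_graph(P, ag_const(image), model$config)
  list(latent = enc$latent$v, latent_aux = enc$latent_aux$v,
       validity_logit = as.numeric(enc$validity$v), aux_logits = enc$aux$v,
       adv_logit = as.numeric(enc$adv$v), features = enc$bottleneck$v)
}

#' Reduce a latent vector to the validity logit
#'
#' The learned fully connected reduction of the latent vector to one raw
#' scalar; squashing (sigmoid) is applied only in losses and reporting.
#'
#' @param model A `larynet_model`.
#' @param latent Numeric vector of length `latent_dim`.
#' @return A single numeric logit.
#' @export
reduce_latent <- function(model, latent) {
  if (length(latent) != model$config$latent_dim)
    stop("latent must have length ", model$config$latent_dim)
  as.numeric(model$params[["val.W"]] %*% latent + model$params[["val.b"]])
}

#' Save / load model checkpoints
#'
#' Checkpoints store the weights, the model configuration, the epoch and the
#' checkpointed metric value.
#'
#' @param model A `larynet_model`.
#' @param path File path.
#' @param epoch,metric Training epoch and metric value to embed.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model`, `epoch` and `metric`.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_, metric = NA_real_) {
  saveRDS(list(params = model$params, config = model$config,
               groups = model$groups, epoch = epoch, metric = metric), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  model <- structure(list(params = x$params, config = x$config,
                          groups = x$groups), class = "larynet_model")
  list(model = model, epoch = x$epoch, metric = x$metric)
}
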