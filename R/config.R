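# Named hyperparameter configurations for the WGAN, and config-file I/O.

.config_fields <- c("name", "latent_dim", "activation", "optimizer",
                    "learning_rate", "dropout", "gen_units", "disc_units",
                    "gcn_units", "batch_size", "batch_size_alt", "gcn_layers",
                    "gp_lambda", "n_critic", "seed")

#' Model configuration
#'
#' All knobs of one generator/discriminator pair. `activation` is
#' `"tanh_relu"` (tanh on the dense stacks, ReLU on the graph-convolution
#' layers) or `"leaky_relu"` (leaky ReLU, slope 0.2, everywhere).
#'
#' @param name label.
#' @param latent_dim width of the noise vector z.
#' @param activation `"tanh_relu"` or `"leaky_relu"`.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param learning_rate step size.
#' @param dropout dropout rate in [0, 1), applied in the critic's dense stack.
#' @param gen_units,disc_units width of the two hidden dense layers.
#' @param gcn_units hidden width of the graph-convolution layers.
#' @param batch_size minibatch size.
#' @param batch_size_alt optional alternative batch size recorded alongside.
#' @param gcn_layers number of relational GCN layers ("several"; default 3).
#' @param gp_lambda gradient-penalty weight (WGAN-GP convention, 10).
#' @param n_critic critic updates per generator update (convention, 5).
#' @param seed weight-initialization seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(name = "custom", latent_dim = 64L,
                         activation = c("tanh_relu", "leaky_relu"),
                         optimizer = c("adam", "rmsprop"),
                         learning_rate = 1e-5, dropout = 0.2,
                         gen_units = 512L, disc_units = 512L,
                         gcn_units = 128L, batch_size = 32L,
                         batch_size_alt = NA_integer_,
                         gcn_layers = 3L, gp_lambda = 10, n_critic = 5L,
                         seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (dropout < 0 || dropout >= 1)
    stop_molwgan("config", "dropout must be in [0, 1)")
  for (f in c("latent_dim", "gen_units", "disc_units", "gcn_units",
              "batch_size", "gcn_layers", "n_critic")) {
    v <- get(f)
    if (!is.numeric(v) || v < 1) stop_molwgan("config", "%s must be positive", f)
  }
  if (learning_rate <= 0) stop_molwgan("config", "learning_rate must be positive")
  if (gp_lambda < 0) stop_molwgan("config", "gp_lambda must be >= 0")
  structure(list(name = name, latent_dim = as.integer(latent_dim),
                 activation = activation, optimizer = optimizer,
                 learning_rate = learning_rate, dropout = dropout,
                 gen_units = as.integer(gen_units),
                 disc_units = as.integer(disc_units),
                 gcn_units = as.integer(gcn_units),
                 batch_size = as.integer(batch_size),
                 batch_size_alt = as.integer(batch_size_alt),
                 gcn_layers = as.integer(gcn_layers),
                 gp_lambda = gp_lambda, n_critic = as.integer(n_critic),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' The four named configurations
#'
#' `"base"`, `"model1"`, `"model2"`, `"model3"`: the tuned hyperparameter
#' columns (latent dimension, activation pairing, optimizer and learning
#' rate, dropout, generator/discriminator units, batch size) used in the
#' study's optimization and fine-tuning stages. Fields the study leaves
#' unstated take documented defaults: `gcn_layers = 3`, `gp_lambda = 10`,
#' `n_critic = 5`. `model3`'s generator/discriminator width is 4092 and its
#' batch size 32, with 512 recorded as `batch_size_alt`.
#'
#' @param name one of `"base"`, `"model1"`, `"model2"`, `"model3"`.
#' @param seed weight-initialization seed carried in the config.
#' @return a `model_config`.
#' @examples
#' make_config("model2")
#' @export
make_config <- function(name, seed = 1L) {
  switch(name,
    base = model_config("base", latent_dim = 64L, activation = "tanh_relu",
                        optimizer = "adam", learning_rate = 1e-5,
                        dropout = 0.2, gen_units = 512L, disc_units = 512L,
                        gcn_units = 128L, batch_size = 32L, seed = seed),
    model1 = model_config("model1", latent_dim = 64L, activation = "leaky_relu",
                          optimizer = "rmsprop", learning_rate = 1e-5,
                          dropout = 0.01, gen_units = 512L, disc_units = 512L,
                          gcn_units = 128L, batch_size = 32L, seed = seed),
    model2 = model_config("model2", latent_dim = 64L, activation = "leaky_relu",
                          optimizer = "rmsprop", learning_rate = 1e-4,
                          dropout = 0.5, gen_units = 512L, disc_units = 512L,
                          gcn_units = 128L, batch_size = 128L, seed = seed),
    model3 = model_config("model3", latent_dim = 256L, activation = "tanh_relu",
                          optimizer = "rmsprop", learning_rate = 1e-4,
                          dropout = 0.5, gen_units = 4092L, disc_units = 4092L,
                          gcn_units = 128L, batch_size = 32L,
                          batch_size_alt = 512L, seed = seed),
    stop_molwgan("config", "unknown configuration name '%s'", name)
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model config '%s'\n", x$name))
  cat(sprintf("  latent %d | %s | %s (lr %g) | dropout %g\n",
              x$latent_dim, x$activation, x$optimizer, x$learning_rate,
              x$dropout))
  cat(sprintf("  units G/D %d/%d | gcn %d x %d | batch %d%s\n",
              x$gen_units, x$disc_units, x$gcn_units, x$gcn_layers,
              x$batch_size,
              if (!is.na(x$batch_size_alt)) sprintf(" (alt %d)", x$batch_size_alt) else ""))
  cat(sprintf("  gp_lambda %g | n_critic %d | seed %d\n",
              x$gp_lambda, x$n_critic, x$seed))
  invisible(x)
}

#' Write / read a model configuration as YAML
#'
#' Field names in the file mirror the `model_config` fields exactly;
#' round-tripping is lossless.
#' @param config a `model_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(model_config, v[setdiff(.config_fields, NULL)][!vapply(v, is.null, TRUE)])
}
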