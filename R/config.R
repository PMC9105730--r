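#' Workflow configuration
#'
#' Bundles every knob of the simulate/train/reconstruct/evaluate workflow and
#' validates cross-field consistency (image size divisible by `2^levels` of
#' both networks, subsampling factors dividing the view count) before any
#' compute happens.
#'
#' @param phantom A [phantom_spec()].
#' @param n_views Full view count (default 96: divisible by the standard
#'   subsampling factors 3, 4, 6, 12 and by `2^levels`).
#' @param factors Integer subsampling factors (default `c(3, 6)`).
#' @param n_train,n_test Dataset sizes.
#' @param netspec_rd,netspec_id [network_spec()]s for the two stages.
#' @param train A [train_spec()].
#' @param filter_name FBP filter.
#' @param out_dir Output directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       n_views = 96L, factors = c(3L, 6L),
                       n_train = 100L, n_test = 20L,
                       netspec_rd = network_spec(channels = c(8L, 16L, 32L)),
                       netspec_id = network_spec(channels = c(8L, 16L, 32L)),
                       train = train_spec(), filter_name = "ram-lak",
                       out_dir = "dualwave-out") {
  cfg <- structure(list(phantom = phantom, n_views = as.integer(n_views),
                        factors = as.integer(factors),
                        n_train = as.integer(n_train),
                        n_test = as.integer(n_test),
                        netspec_rd = netspec_rd, netspec_id = netspec_id,
                        train = train, filter_name = filter_name,
                        out_dir = out_dir),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  problems <- character()
  mult <- 2L^max(cfg$netspec_rd$levels, cfg$netspec_id$levels)
  if (cfg$phantom$size %% mult != 0L)
    problems <- c(problems, sprintf(
      "phantom size %d not divisible by 2^levels = %d", cfg$phantom$size, mult))
  if (cfg$n_views %% mult != 0L)
    problems <- c(problems, sprintf(
      "n_views %d not divisible by 2^levels = %d (sinogram enters the radon network)",
      cfg$n_views, mult))
  bad <- cfg$factors[cfg$n_views %% cfg$factors != 0L]
  if (length(bad))
    problems <- c(problems, sprintf("factor %d does not divide n_views %d",
                                    bad, cfg$n_views))
  if (length(problems))
    stop("invalid run_config:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' Write a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path written by [write_run_config()].
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    phantom = do.call(phantom_spec, y$phantom[c("size", "n_ellipses",
                                                "intensity_range", "seed")]),
    n_views = y$n_views, factors = y$factors,
    n_train = y$n_train, n_test = y$n_test,
    netspec_rd = spec_from_list(y$netspec_rd),
    netspec_id = spec_from_list(y$netspec_id),
    train = do.call(train_spec, y$train[c("lr", "beta1", "beta2",
                                          "batch_size", "lr_decay",
                                          "decay_every", "epochs", "seed")]),
    filter_name = y$filter_name, out_dir = y$out_dir)
}

spec_from_list <- function(l) {
  network_spec(levels = l$levels, block_depth = l$block_depth,
               channels = l$channels, downsample = l$downsample,
               residual = l$residual, in_channels = l$in_channels)
}
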