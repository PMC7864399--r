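# Serialization: networks and states as JSON (text, portable), images as
# PNG, run configurations as YAML/JSON.

#' Write a network to a JSON file
#'
#' Atoms are stored flattened with their dimensions, alongside strides and
#' sparsity penalties, in plain text.
#'
#' @param network An [sdpc_network()].
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  obj <- list(
    lambda = network$lambda,
    layers = lapply(network$dictionaries, function(d)
      list(dim = dim(d$atoms), stride = d$stride,
           atoms = as.vector(d$atoms))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path JSON file path.
#' @return An [sdpc_network()].
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dicts <- lapply(seq_len(nrow_or_len(obj$layers)), function(i) {
    ly <- pick_row(obj$layers, i)
    sdpc_dictionary(array(ly$atoms, dim = ly$dim), stride = ly$stride,
                    normalize = FALSE)
  })
  sdpc_network(dicts, obj$lambda)
}

# jsonlite may simplify a homogeneous list of layers to a data frame.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
pick_row <- function(x, i) {
  if (is.data.frame(x))
    list(dim = x$dim[[i]], stride = x$stride[[i]], atoms = x$atoms[[i]])
  else x[[i]]
}

#' Read an image file as a channel-first array
#'
#' @param path PNG file path.
#' @return Matrix (grayscale) or `[channels, W, H]` array, values in
#'   `[0, 1]`; the first spatial axis is the image column (x), matching
#'   the package's `[channel, x, y]` convention.
#' @export
read_image <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 2L) return(t(im))
  aperm(im, c(3, 2, 1))
}

#' Write a channel-first image array as PNG
#'
#' Values are affinely rescaled to `[0, 1]`.
#'
#' @param image Matrix or `[channels, W, H]` array (1, 3 or 4 channels).
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  x <- as_activity(image)
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  out <- if (dim(x)[1] == 1L) t(x[1, , ]) else aperm(x, c(3, 2, 1))
  png::writePNG(out, path)
  invisible(path)
}

# Allowed keys of a run configuration file and their handlers.
run_config_schema <- function() {
  c("layers", "lambda", "k_fb", "t_fp", "max_iter", "epochs", "lr",
    "momentum", "batch_size", "seed", "sigma_grid", "k_fb_grid",
    "lambda1_grid", "n_images", "image_size", "n_features_l1",
    "n_features_l2", "kernel", "strides", "n_active", "noise_sd")
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected with an error naming them; the schema mirrors
#' the network/training/sweep parameters of the package's constructors.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @param required Keys that must be present.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path, required = character()) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), run_config_schema())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("missing configuration key(s): ", paste(missing, collapse = ", "))
  cfg
}
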