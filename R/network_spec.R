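#' Network architecture specifications
#'
#' A `network_spec` is a lightweight, framework-free description of a network:
#' an ordered table of layer descriptors (name, kind, output shape, trainable
#' and total parameter counts) that can be queried by layer name and printed
#' as a summary table. It is built analytically from a configuration, so the
#' architecture trace (shapes and parameter counts) can be inspected and
#' tested without instantiating any weights.
#'
#' Batch-normalization layers report 4 parameters per channel: scale and
#' offset (trainable) plus the two moving statistics.
#'
#' @param layers data.frame with columns `name`, `kind`, `params`, and a list
#'   column `dims` of integer output shapes (excluding the batch dimension).
#' @param config the configuration list the spec was built from.
#' @return An object of class `network_spec`.
#' @keywords internal
new_network_spec <- function(layers, config = NULL) {
  stopifnot(is.data.frame(layers),
            all(c("name", "kind", "params", "dims") %in% names(layers)))
  structure(list(layers = layers, config = config,
                 total_parameters = sum(layers$params)),
            class = "network_spec")
}

spec_row <- function(name, kind, dims, params = 0) {
  data.frame(name = name, kind = kind, params = as.numeric(params),
             dims = I(list(as.integer(dims))), stringsAsFactors = FALSE)
}

#' Query a layer descriptor by name
#'
#' @param spec a `network_spec`.
#' @param name layer name.
#' @return A list with `name`, `kind`, `output_shape` (integer vector, batch
#'   dimension excluded) and `params`.
#' @export
spec_layer <- function(spec, name) {
  stopifnot(inherits(spec, "network_spec"))
  i <- match(name, spec$layers$name)
  if (is.na(i)) stop("no layer named '", name, "' in this network spec")
  list(name = name, kind = spec$layers$kind[i],
       output_shape = spec$layers$dims[[i]],
       params = spec$layers$params[i])
}

#' Total parameter count of a network spec
#' @param spec a `network_spec`.
#' @return Numeric scalar.
#' @export
spec_total_params <- function(spec) spec$total_parameters

shape_str <- function(d) paste0("(None, ", paste(d, collapse = ", "), ")")

#' @export
format.network_spec <- function(x, ...) {
  ly <- x$layers
  out <- data.frame(layer = ly$name, kind = ly$kind,
                    output_shape = vapply(ly$dims, shape_str, character(1)),
                    params = format(ly$params, big.mark = ",", trim = TRUE))
  c(sprintf("network_spec: %d layers, %s parameters", nrow(ly),
            format(x$total_parameters, big.mark = ",")),
    utils::capture.output(print(out, row.names = FALSE)))
}

#' @export
print.network_spec <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
as.data.frame.network_spec <- function(x, ...) {
  data.frame(name = x$layers$name, kind = x$layers$kind,
             output_shape = vapply(x$layers$dims, shape_str, character(1)),
             params = x$layers$params, stringsAsFactors = FALSE)
}
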