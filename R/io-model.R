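# Model-system document I/O.
#
# A model system is stored as a single versioned JSON document with keys
# `schema`, `modes`, `cubic`, `quartic`, `coriolis`, `surfaces`, `metadata`.
# Mode indices are 1-based in the file.  Numbers are written with 17
# significant digits so that a write/read round trip reproduces every double
# bit-exactly.

.MODEL_SCHEMA <- "anharmvoa-model-1"

#' Write a model system to a JSON document
#'
#' @param system a [model_system()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_model_system()]
#' @export
write_model_system <- function(system, path) {
  stopifnot(inherits(system, "model_system"))
  ff <- system$force_field
  doc <- list(
    schema = .MODEL_SCHEMA,
    modes = list(omega = ff$modes$omega, labels = ff$modes$labels),
    cubic = as.list(ff$cubic),
    quartic = as.list(ff$quartic),
    coriolis = if (!is.null(system$coriolis)) list(
      zeta = system$coriolis$zeta,
      rotational_constants = system$coriolis$rotational_constants
    ),
    surfaces = lapply(system$surfaces, function(s) list(
      name = s$name, value0 = s$value0, d1 = s$d1, d2 = s$d2,
      d3 = as.list(s$d3)
    )),
    metadata = system$metadata
  )
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model system from a JSON document
#'
#' @param path path to a document written by [write_model_system()].
#' @return A [model_system()].
#' @export
read_model_system <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(doc$schema, .MODEL_SCHEMA))
    stop("unrecognized model-system schema: ", doc$schema)
  modes <- normal_modes(doc$modes$omega, doc$modes$labels)
  nm <- modes$n_modes
  ff <- quartic_force_field(modes)
  for (k in names(doc$cubic)) ff <- ff_set_constant(ff, .key_idx(k), doc$cubic[[k]])
  for (k in names(doc$quartic)) ff <- ff_set_constant(ff, .key_idx(k), doc$quartic[[k]])
  coriolis <- NULL
  if (!is.null(doc$coriolis) && length(doc$coriolis)) {
    zeta <- array(unlist(doc$coriolis$zeta), dim = c(3, nm, nm))
    coriolis <- coriolis_data(zeta, doc$coriolis$rotational_constants)
  }
  surfaces <- lapply(doc$surfaces, function(s) {
    nc <- .surface_shapes[[s$name]]
    property_surface(
      s$name, n_modes = nm,
      value0 = s$value0,
      d1 = matrix(unlist(s$d1), nc, nm),
      d2 = array(unlist(s$d2), c(nc, nm, nm)),
      d3 = lapply(s$d3, as.numeric)
    )
  })
  metadata <- if (is.null(doc$metadata)) list() else doc$metadata
  model_system(ff, surfaces = unname(surfaces), coriolis = coriolis,
               metadata = metadata)
}
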