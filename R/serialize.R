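#' Serialize activation models to JSON
#'
#' Writes a versioned, plain-text JSON representation of one model, a list of
#' models, or a whole \code{\link{sigact}} fit (its models). Probabilities are
#' written at full precision so a reloaded model predicts identically.
#'
#' @param object A \code{sigact} fit, a \code{sigact_model}, or a list of
#'   models.
#' @param path Output file path.
#' @export
write_models <- function(object, path) {
  if (inherits(object, "sigact")) object <- object$models
  if (inherits(object, "sigact_model")) object <- list(object)
  payload <- list(
    schema_version = 1L,
    models = lapply(unname(object), function(m) {
      list(signature_id = m$signature_id, K = m$K,
           rules = m$rules[, c("gene_x", "gene_y", "target_class")],
           cond_prob_true = as.list(as.data.frame(m$cond_prob)),
           priors = as.list(m$priors),
           retained = if (is.na(m$retained)) NULL else m$retained,
           meta = m$meta)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load activation models from JSON
#'
#' @param path Path written by \code{\link{write_models}}.
#' @return A named list of \code{\link{sigact_model}} objects.
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$schema_version) || payload$schema_version != 1L)
    stop("read_models: unsupported or missing schema_version in '", path, "'")
  models <- lapply(payload$models, function(m) {
    cond <- vapply(activation_levels(), function(lv)
      as.numeric(unlist(m$cond_prob_true[[lv]])), numeric(as.integer(m$K)))
    cond <- matrix(cond, nrow = as.integer(m$K),
                   dimnames = list(NULL, activation_levels()))
    rules <- do.call(rbind, lapply(m$rules, function(r)
      data.frame(gene_x = r$gene_x, gene_y = r$gene_y,
                 target_class = r$target_class, stringsAsFactors = FALSE)))
    sigact_model(m$signature_id, rules = rules, cond_prob = cond,
                 priors = vapply(activation_levels(),
                                 function(lv) as.numeric(m$priors[[lv]]), 0),
                 K = as.integer(m$K),
                 retained = if (is.null(m$retained)) NA else m$retained,
                 meta = if (is.null(m$meta)) list() else m$meta)
  })
  names(models) <- vapply(models, `[[`, "", "signature_id")
  models
}
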