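# Reading stoichiometric models (tab-separated tables or SBML L3/FBC) and
# round-tripping sample chains as delimited text with a JSON metadata header.

#' Construct and validate a stoichiometric model
#'
#' A model is the constraint set `S v = 0`, `lb <= v <= ub`: `S` has one row
#' per metabolite and one column per reaction, and the bounds encode
#' irreversibility, kinetic limits and nutrient availability (arbitrary flux
#' units, e.g. mmol/gDW/h).
#'
#' @param S numeric M x N stoichiometric matrix.
#' @param metabolite_ids,reaction_ids unique id vectors matching the rows and
#'   columns of `S`.
#' @param lower_bounds,upper_bounds length-N flux bounds with
#'   `lower_bounds <= upper_bounds`.
#' @return object of class `stoich_model`.
#' @examples
#' m <- stoich_model(matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE),
#'                   c("A", "B"), c("R1", "R2", "R3"),
#'                   rep(0, 3), rep(10, 3))
#' @export
stoich_model <- function(S, metabolite_ids, reaction_ids,
                         lower_bounds, upper_bounds) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != length(metabolite_ids))
    stop("S has ", nrow(S), " rows but ", length(metabolite_ids),
         " metabolite ids", call. = FALSE)
  if (ncol(S) != length(reaction_ids))
    stop("S has ", ncol(S), " columns but ", length(reaction_ids),
         " reaction ids", call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]),
               collapse = ", "), call. = FALSE)
  lower_bounds <- as.numeric(lower_bounds)
  upper_bounds <- as.numeric(upper_bounds)
  if (length(lower_bounds) != ncol(S) || length(upper_bounds) != ncol(S))
    stop("bounds must have one entry per reaction", call. = FALSE)
  bad <- which(lower_bounds > upper_bounds)
  if (length(bad))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reaction_ids[bad], collapse = ", "), call. = FALSE)
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  structure(list(S = S,
                 metabolite_ids = as.character(metabolite_ids),
                 reaction_ids = as.character(reaction_ids),
                 lower_bounds = lower_bounds,
                 upper_bounds = upper_bounds),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", length(x$metabolite_ids), " metabolites, ",
      length(x$reaction_ids), " reactions\n", sep = "")
  invisible(x)
}

#' Read a stoichiometric model from disk
#'
#' Two encodings are supported. `format = "table"`: a tab-separated
#' stoichiometry matrix whose header row holds reaction ids and whose first
#' column holds metabolite ids (`#` starts a comment), plus a companion
#' bounds table with columns `reaction`, `lower`, `upper`. Reactions missing
#' from the bounds table get `(-default_bound, default_bound)` with a
#' warning. `format = "sbml"`: SBML Level 3 with the FBC flux-bound package
#' (read only; gene rules, compartments and objectives are ignored).
#'
#' @param path model file (stoichiometry table, or SBML file).
#' @param format `"table"` or `"sbml"`.
#' @param bounds_path companion bounds table (table format only; optional).
#' @param default_bound magnitude used when a bound is missing; the sampled
#'   polytope must be bounded, so missing bounds become a large finite box.
#' @return a validated [stoich_model()].
#' @export
read_model <- function(path, format = c("table", "sbml"), bounds_path = NULL,
                       default_bound = .fluxhr_defaults$default_bound) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "table") {
    read_model_table(path, bounds_path, default_bound)
  } else {
    read_model_sbml(path, default_bound)
  }
}

read_model_table <- function(path, bounds_path, default_bound) {
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, row.names = 1),
    error = function(e) stop("cannot parse stoichiometry table '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  S <- as.matrix(tab)
  if (!is.numeric(S))
    stop("non-numeric stoichiometric coefficients in '", path, "'",
         call. = FALSE)
  rxn <- colnames(S)
  met <- rownames(S)
  lb <- rep(-default_bound, ncol(S))
  ub <- rep(default_bound, ncol(S))
  if (!is.null(bounds_path)) {
    if (!file.exists(bounds_path))
      stop("bounds file not found: ", bounds_path, call. = FALSE)
    bt <- tryCatch(
      utils::read.table(bounds_path, header = TRUE, sep = "\t",
                        comment.char = "#", stringsAsFactors = FALSE),
      error = function(e) stop("cannot parse bounds table '", bounds_path,
                               "': ", conditionMessage(e), call. = FALSE))
    need <- c("reaction", "lower", "upper")
    if (!all(need %in% names(bt)))
      stop("bounds table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    unknown <- setdiff(bt$reaction, rxn)
    if (length(unknown))
      stop("bounds for unknown reaction(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    idx <- match(bt$reaction, rxn)
    lb[idx] <- as.numeric(bt$lower)
    ub[idx] <- as.numeric(bt$upper)
    missing <- setdiff(rxn, bt$reaction)
    if (length(missing))
      warning("no bounds for reaction(s) ", paste(missing, collapse = ", "),
              "; using (-", default_bound, ", ", default_bound, ")",
              call. = FALSE)
  } else {
    warning("no bounds table given; all reactions bounded by (-",
            default_bound, ", ", default_bound, ")", call. = FALSE)
  }
  stoich_model(S, met, rxn, lb, ub)
}

read_model_sbml <- function(path, default_bound) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  model <- xml2::xml_find_first(doc, ".//*[local-name() = 'model']")
  if (inherits(model, "xml_missing"))
    stop("no <model> element in '", path, "'", call. = FALSE)

  sp <- xml2::xml_find_all(model,
        ".//*[local-name() = 'listOfSpecies']/*[local-name() = 'species']")
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  met <- xml2::xml_attr(sp, "id")[keep]
  if (!length(met)) stop("no species in '", path, "'", call. = FALSE)

  pars <- xml2::xml_find_all(model,
        ".//*[local-name() = 'listOfParameters']/*[local-name() = 'parameter']")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(model,
        ".//*[local-name() = 'listOfReactions']/*[local-name() = 'reaction']")
  if (!length(rx)) stop("no reactions in '", path, "'", call. = FALSE)
  rxn <- xml2::xml_attr(rx, "id")

  S <- matrix(0, length(met), length(rxn), dimnames = list(met, rxn))
  lb <- rep(NA_real_, length(rxn))
  ub <- rep(NA_real_, length(rxn))
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[j]],
        paste0("./*[local-name() = '", side,
               "']/*[local-name() = 'speciesReference']"))
      if (!length(refs)) next
      ids <- xml2::xml_attr(refs, "species")
      sto <- xml2::xml_attr(refs, "stoichiometry")
      sto <- ifelse(is.na(sto), 1, as.numeric(sto))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (k in seq_along(ids)) {
        if (ids[k] %in% met) S[ids[k], j] <- S[ids[k], j] + sgn * sto[k]
      }
    }
    # xml2 resolves namespaced attributes by their local name
    lbid <- xml2::xml_attr(rx[[j]], "lowerFluxBound")
    ubid <- xml2::xml_attr(rx[[j]], "upperFluxBound")
    if (is.na(lbid)) lbid <- xml2::xml_attr(rx[[j]], "fbc:lowerFluxBound")
    if (is.na(ubid)) ubid <- xml2::xml_attr(rx[[j]], "fbc:upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(parval)) lb[j] <- parval[[lbid]]
    if (!is.na(ubid) && ubid %in% names(parval)) ub[j] <- parval[[ubid]]
    if (is.na(lb[j]) || is.na(ub[j])) {
      rev <- identical(xml2::xml_attr(rx[[j]], "reversible"), "true")
      if (is.na(lb[j])) lb[j] <- if (rev) -default_bound else 0
      if (is.na(ub[j])) ub[j] <- default_bound
      warning("missing FBC bound(s) for reaction ", rxn[j],
              "; defaulted", call. = FALSE)
    }
  }
  lb[!is.finite(lb)] <- -default_bound
  ub[!is.finite(ub)] <- default_bound
  # drop metabolites that never occur (boundary-only species)
  used <- rowSums(S != 0) > 0
  stoich_model(S[used, , drop = FALSE], met[used], rxn, lb, ub)
}

#' Write a model as a stoichiometry table plus bounds table
#'
#' Inverse of the `"table"` branch of [read_model()]; used to materialize toy
#' models for round-trip checks and command-line runs.
#'
#' @param model a [stoich_model()].
#' @param path,bounds_path output file paths.
#' @export
write_model_table <- function(model, path, bounds_path) {
  df <- data.frame(metabolite = model$metabolite_ids,
                   model$S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bt <- data.frame(reaction = model$reaction_ids,
                   lower = model$lower_bounds, upper = model$upper_bounds)
  utils::write.table(bt, bounds_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

# ---- sample chains --------------------------------------------------------

#' Construct a sample chain
#'
#' Ordered Monte Carlo states in the full-dimensional coordinates of a
#' polytope, with provenance (sampler id, seed, thinning).
#'
#' @param points T x D numeric matrix, rows ordered by Monte Carlo time.
#' @param sampler_id one of `"hr"`, `"hr_rounded"`, `"achr"`, `"rejection"`.
#' @param seed integer RNG seed the chain was generated with.
#' @param thinning recorded-every-k steps (k >= 1); recorded, not reapplied.
#' @param labels coordinate labels.
#' @param ellipsoid_ref optional identifier of the biasing ellipsoid.
#' @param resamples count of degenerate-chord direction resamples.
#' @return object of class `sample_chain`.
#' @export
sample_chain <- function(points, sampler_id, seed, thinning = 1L,
                         labels = NULL, ellipsoid_ref = NULL, resamples = 0) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 1) stop("empty chain", call. = FALSE)
  sampler_id <- match.arg(sampler_id, c("hr", "hr_rounded", "achr",
                                        "rejection"))
  if (is.null(labels)) labels <- paste0("p", seq_len(ncol(points)))
  stopifnot(length(labels) == ncol(points), thinning >= 1)
  colnames(points) <- labels
  structure(list(points = points, sampler_id = sampler_id,
                 seed = as.integer(seed), thinning = as.integer(thinning),
                 labels = labels, ellipsoid_ref = ellipsoid_ref,
                 resamples = resamples),
            class = "sample_chain")
}

#' @export
print.sample_chain <- function(x, ...) {
  cat("<sample_chain> ", nrow(x$points), " points, D = ", ncol(x$points),
      ", sampler = ", x$sampler_id, ", seed = ", x$seed,
      ", thinning = ", x$thinning, "\n", sep = "")
  invisible(x)
}

#' Write / read a sample chain as delimited text
#'
#' The container is a tab-separated numeric table preceded by one
#' `# fluxhr-chain {...}` JSON metadata line (sampler id, seed, thinning,
#' labels), so chains are diffable and round-trip losslessly: numbers are
#' written with full round-trip precision.
#'
#' @param chain a [sample_chain()].
#' @param path file path.
#' @return `read_chain()` returns the reconstructed [sample_chain()].
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "sample_chain"))
  meta <- list(sampler_id = chain$sampler_id, seed = chain$seed,
               thinning = chain$thinning, labels = as.list(chain$labels),
               resamples = chain$resamples)
  if (!is.null(chain$ellipsoid_ref)) meta$ellipsoid_ref <- chain$ellipsoid_ref
  header <- paste0("# fluxhr-chain ",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  txt <- matrix(sprintf("%.17g", chain$points), nrow = nrow(chain$points))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(chain$labels, collapse = "\t"), con)
  writeLines(apply(txt, 1, paste, collapse = "\t"), con)
  invisible(NULL)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# fluxhr-chain "))
    stop("'", path, "' is not a fluxhr chain file", call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^# fluxhr-chain ", "", first))
  dt <- data.table::fread(path, skip = 1, sep = "\t", header = TRUE)
  pts <- as.matrix(dt)
  sample_chain(pts, meta$sampler_id, meta$seed, meta$thinning,
               labels = unlist(meta$labels),
               ellipsoid_ref = meta$ellipsoid_ref,
               resamples = if (is.null(meta$resamples)) 0 else meta$resamples)
}
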