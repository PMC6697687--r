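#' Read and write model bundles
#'
#' A model bundle is a JSON file with keys `species` (array of names),
#' `steady_state` (array of numbers), `jacobian` (row-major nested arrays)
#' and `model_id`. The round trip `read_model(write_model(m))` is bit-exact:
#' numbers are serialized at full precision. The evaluable `rhs` of a
#' generated model is not serialized (functions are not data); a reloaded
#' model supports everything except the ODE oracle.
#'
#' @param model a [dynamical_model()].
#' @param path file path; `.json` bundle, or `.csv` matrix (header row of
#'   species names) with steady state stored as a `#steady_state:` comment.
#' @return `read_model` returns a `dynamical_model`; `write_model` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dynamical_model"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#model_id: ", model$model_id), con)
    writeLines(paste0("#steady_state: ",
                      paste(sprintf("%.17g", model$steady_state),
                            collapse = ",")), con)
    writeLines(paste(model$species, collapse = ","), con)
    apply(model$jacobian, 1, function(r) {
      writeLines(paste(sprintf("%.17g", r), collapse = ","), con)
    })
  } else {
    obj <- list(model_id = model$model_id,
                species = model$species,
                steady_state = model$steady_state,
                jacobian = apply(model$jacobian, 1, identity,
                                 simplify = FALSE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    body <- grep("^#", lines, value = TRUE, invert = TRUE)
    model_id <- sub("^#model_id: *", "", grep("^#model_id:", meta, value = TRUE))
    ss_line <- sub("^#steady_state: *", "",
                   grep("^#steady_state:", meta, value = TRUE))
    species <- strsplit(body[1], ",")[[1]]
    rows <- lapply(seq_along(body)[-1], function(k) {
      vals <- suppressWarnings(as.numeric(strsplit(body[k], ",")[[1]]))
      if (length(vals) != length(species) || any(is.na(vals))) {
        stop("parse error at line ", k + length(meta), ": expected ",
             length(species), " numeric fields, got row of length ",
             length(strsplit(body[k], ",")[[1]]))
      }
      vals
    })
    if (length(rows) != length(species)) {
      stop("parse error: matrix is ", length(rows), " x ", length(species),
           ", expected square")
    }
    J <- do.call(rbind, rows)
    ss <- if (length(ss_line)) as.numeric(strsplit(ss_line, ",")[[1]])
          else rep(1, length(species))
    dynamical_model(J, steady_state = ss, species = species,
                    model_id = if (length(model_id)) model_id else "model")
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (key in c("species", "steady_state", "jacobian")) {
      if (is.null(obj[[key]])) stop("model bundle is missing key '", key, "'")
    }
    J <- obj$jacobian
    if (is.list(J)) J <- do.call(rbind, lapply(J, as.numeric))
    J <- as.matrix(J)
    if (nrow(J) != ncol(J) || nrow(J) != length(obj$species)) {
      stop("parse error: jacobian is ", nrow(J), " x ", ncol(J),
           " for ", length(obj$species), " species")
    }
    dynamical_model(J, steady_state = as.numeric(obj$steady_state),
                    species = as.character(obj$species),
                    model_id = if (!is.null(obj$model_id)) obj$model_id
                               else "model")
  }
}

#' Read and write influence networks as TSV edge lists
#'
#' Columns: `source_name`, `target_name`, `sign`, `weight`, with a header
#' row. A duplicated (source, target) pair is resolved last-wins with a
#' warning.
#'
#' @param network an [influence_network()].
#' @param path TSV file path.
#' @param nodes optional full node-name vector for `read_network` so that
#'   isolated nodes survive the round trip; defaults to the names appearing
#'   in the edge list.
#' @return `read_network` returns an `influence_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "influence_network"))
  df <- data.frame(source_name = network$nodes[network$edges$from],
                   target_name = network$nodes[network$edges$to],
                   sign = network$edges$sign,
                   weight = sprintf("%.17g", network$edges$weight))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, nodes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("source_name", "target_name", "sign", "weight")
  if (!all(need %in% names(df))) {
    stop("parse error: expected columns ", paste(need, collapse = ", "))
  }
  key <- paste(df$source_name, df$target_name, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges in ", path, "; keeping the last occurrence")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(df$source_name, df$target_name)))
  miss <- setdiff(c(df$source_name, df$target_name), nodes)
  if (length(miss)) stop("edge names not in node set: ",
                         paste(miss, collapse = ", "))
  influence_network(
    n_nodes = length(nodes),
    edges = data.frame(from = match(df$source_name, nodes),
                       to = match(df$target_name, nodes),
                       sign = as.numeric(df$sign),
                       weight = as.numeric(df$weight)),
    nodes = nodes,
    model_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a square matrix as CSV with species-name header
#'
#' Full-precision (`%.17g`) CSV so that read-back agrees to 1e-15.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("s", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nm, collapse = ","), con)
  apply(m, 1, function(r) {
    writeLines(paste(sprintf("%.17g", r), collapse = ","), con)
  })
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  lines <- readLines(path)
  nm <- strsplit(lines[1], ",")[[1]]
  rows <- lapply(seq_along(lines)[-1], function(k) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[k], ",")[[1]]))
    if (length(vals) != length(nm) || any(is.na(vals) & !is.nan(vals))) {
      stop("parse error at line ", k, ": expected ", length(nm),
           " numeric fields")
    }
    vals
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(nm[seq_len(nrow(m))], nm)
  m
}
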