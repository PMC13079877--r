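# Per-component molecular embeddings.
#
# Two backends are defined.  The default "synthetic" backend maps the
# canonical SMILES through SHA-256 to a seed and draws a standard-normal
# vector: identical molecules (identical canonical SMILES) get bitwise
# identical embeddings, with no model download.  A "chemberta" backend slot
# exists for transformer embeddings but is not bundled; requesting it raises
# an actionable error pointing at the synthetic backend.

#' Canonicalize a SMILES string
#'
#' Uses Open Babel (via ChemmineOB) to parse and canonicalize, so different
#' spellings of the same molecule ("OCC", "CCO") collapse to one string.
#'
#' @param smiles a single SMILES string
#' @return the canonical SMILES
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- suppressWarnings(try(
    utils::capture.output(
      res <- ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
      type = "message"),
    silent = TRUE))
  if (inherits(out, "try-error")) res <- ""
  res <- sub("[ \t\r\n].*$", "", res)
  if (!nzchar(res))
    stop(sprintf("could not parse SMILES string '%s'", smiles))
  res
}

#' Embed a pure component
#'
#' @param smiles SMILES string of the component
#' @param backend `"synthetic"` (default) or `"chemberta"`
#' @param D embedding dimension; defaults to 16 for the synthetic backend and
#'   384 (the published hidden size of the named transformer variant) for
#'   `"chemberta"`
#' @param component_id identifier; defaults to the canonical SMILES
#' @param name optional display name
#' @return a `component_record` list with fields `component_id`, `smiles`
#'   (canonical), `embedding`, `name`
#' @examples
#' a <- embed_component("OCC")
#' b <- embed_component("CCO")
#' identical(a$embedding, b$embedding)
#' @export
embed_component <- function(smiles, backend = c("synthetic", "chemberta"),
                            D = NULL, component_id = NULL, name = NULL) {
  backend <- match.arg(backend)
  can <- canonical_smiles(smiles)
  if (backend == "chemberta") {
    stop("the 'chemberta' backend requires a bundled transformer model, ",
         "which this installation does not provide; use backend = 'synthetic' ",
         "for reproducible hash-seeded embeddings")
  }
  if (is.null(D)) D <- 16L
  emb <- synthetic_embedding(can, D)
  structure(list(component_id = if (is.null(component_id)) can else component_id,
                 smiles = can, embedding = emb, name = name),
            class = "component_record")
}

# Deterministic standard-normal vector seeded by SHA-256 of a string.
synthetic_embedding <- function(key, D) {
  seed <- strtoi(substr(digest::digest(key, algo = "sha256",
                                       serialize = FALSE), 1L, 7L), base = 16L)
  with_seed(seed, stats::rnorm(D))
}

#' Generate fictitious components with embeddings
#'
#' Creates `n` synthetic pure components whose embeddings are hash-seeded
#' from their ids (no SMILES involved), plus Antoine vapor-pressure
#' coefficients drawn so that normal boiling points fall in 300-420 K.  These
#' components back the synthetic datasets: their ground-truth mixture
#' parameters are later derived from these embeddings (see
#' [sample_systems()]), which is what makes property prediction from the
#' embedding learnable.
#'
#' @param n number of components
#' @param D embedding dimension
#' @param seed integer seed
#' @return a components data frame (one row per component; embedding in
#'   columns `emb_0` .. `emb_{D-1}`, Antoine coefficients in `antoine_a/b/c`)
#' @export
synthetic_components <- function(n, D = 16L, seed = 1L) {
  ids <- sprintf("SYN%03d", seq_len(n))
  emb <- vapply(ids, function(id)
    synthetic_embedding(paste0("component:", id, ":", seed), D), numeric(D))
  with_seed(child_seed(seed, "antoine"), {
    A  <- stats::runif(n, 3.9, 4.35)
    Tb <- stats::runif(n, 300, 420)
    Cc <- rep(-43, n)
    B  <- (A - log10(1.01325)) * (Tb + Cc)
  })
  df <- data.frame(component_id = ids, smiles = NA_character_,
                   name = ids, stringsAsFactors = FALSE)
  embdf <- as.data.frame(t(emb))
  names(embdf) <- paste0("emb_", seq_len(D) - 1L)
  rownames(embdf) <- NULL
  cbind(df, embdf, antoine_a = A, antoine_b = B, antoine_c = Cc)
}

#' Build a components data frame from component records
#'
#' @param records list of `component_record` objects (see [embed_component()])
#' @return components data frame with `emb_*` columns
#' @export
components_frame <- function(records) {
  D <- length(records[[1]]$embedding)
  stopifnot(all(vapply(records, function(r) length(r$embedding), 1L) == D))
  emb <- vapply(records, `[[`, numeric(D), "embedding")
  if (!is.matrix(emb)) emb <- matrix(emb, nrow = D)
  df <- data.frame(
    component_id = vapply(records, `[[`, "", "component_id"),
    smiles = vapply(records, function(r) if (is.null(r$smiles)) NA_character_ else r$smiles, ""),
    name = vapply(records, function(r) if (is.null(r$name)) NA_character_ else r$name, ""),
    stringsAsFactors = FALSE)
  embdf <- as.data.frame(t(emb))
  names(embdf) <- paste0("emb_", seq_len(D) - 1L)
  rownames(embdf) <- NULL
  cbind(df, embdf)
}

# D x n embedding matrix (columns named by component_id) from a components
# data frame.
embedding_matrix <- function(components) {
  ec <- grep("^emb_", names(components), value = TRUE)
  ec <- ec[order(as.integer(sub("^emb_", "", ec)))]
  if (!length(ec)) stop("components frame has no emb_* columns")
  E <- t(as.matrix(components[, ec, drop = FALSE]))
  if (any(!is.finite(E))) stop("embeddings must be finite")
  colnames(E) <- components$component_id
  rownames(E) <- NULL
  E
}

#' Read / write a components file
#'
#' CSV with header `component_id,smiles,name[,emb_0..emb_{D-1}]` (plus
#' optional `antoine_a/b/c` columns for synthetic components).  If the
#' embedding columns are absent they are computed from the SMILES with the
#' synthetic backend.
#'
#' @param path file path
#' @param D embedding dimension used when embeddings must be computed
#' @return a components data frame
#' @export
read_components <- function(path, D = 16L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("component_id", "smiles") %in% names(df)))
  if (!any(grepl("^emb_", names(df)))) {
    recs <- lapply(seq_len(nrow(df)), function(i)
      embed_component(df$smiles[i], D = D, component_id = df$component_id[i],
                      name = if ("name" %in% names(df)) df$name[i] else NULL))
    emb <- components_frame(recs)
    df <- cbind(df, emb[, grep("^emb_", names(emb)), drop = FALSE])
  }
  df
}

#' @rdname read_components
#' @param components components data frame
#' @export
write_components <- function(components, path) {
  utils::write.csv(components, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
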