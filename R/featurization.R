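#' Fingerprint view specification
#'
#' The three hashed substructure fingerprints used for modelling:
#' Avalon (path enumeration, binary), Morgan (circular environments,
#' binary, radius 2 by convention) and AtomPair (topological atom pairs,
#' count-valued). All are hashed to a fixed width, 1024 by default.
#'
#' @param name One of `"avalon"`, `"atompair"`, `"morgan"`.
#' @param width Positive integer fingerprint width.
#' @param radius Morgan radius (ignored by the other views).
#' @return A `view_spec` with fields `name`, `width`, `value_kind`
#'   (`"boolean"` for avalon/morgan, `"count"` for atompair) and `radius`.
#' @export
view_spec <- function(name = c("avalon", "atompair", "morgan"),
                      width = 1024L, radius = 2L) {
  name <- match.arg(name)
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop_cffat("width must be a positive integer")
  structure(
    list(name = name, width = width,
         value_kind = if (name == "atompair") "count" else "boolean",
         radius = as.integer(radius)),
    class = "view_spec"
  )
}

fingerprint_script <- function() {
  path <- system.file("python", "fingerprints.py", package = "cffat")
  if (!nzchar(path)) stop_cffat("bundled fingerprint script not found")
  path
}

python_binary <- function() {
  bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) stop_cffat("no python interpreter on PATH (needed for RDKit fingerprints)")
  bin
}

# Run the RDKit helper over a batch of SMILES. Returns a data frame with
# columns ok (logical), bits (list of integer index:value pairs).
run_fingerprinter <- function(smiles, view) {
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)))
  writeLines(smiles, infile)
  status <- system2(
    python_binary(),
    c(fingerprint_script(), "--view", view$name, "--width", view$width,
      "--radius", view$radius, "--in", shQuote(infile), "--out", shQuote(outfile)),
    stdout = TRUE, stderr = TRUE
  )
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop_cffat("fingerprint backend failed: %s", paste(status, collapse = "\n"))
  }
  utils::read.delim(outfile, header = FALSE, sep = "\t",
                    col.names = c("ok", "bits"),
                    colClasses = c("integer", "character"))
}

decode_bits <- function(encoded, width) {
  v <- numeric(width)
  if (!nzchar(encoded)) return(v)
  for (pair in strsplit(encoded, ",", fixed = TRUE)[[1]]) {
    kv <- strsplit(pair, ":", fixed = TRUE)[[1]]
    v[as.integer(kv[1]) + 1L] <- as.numeric(kv[2])
  }
  v
}

#' Fingerprint a single SMILES string
#'
#' @param smiles A SMILES string.
#' @param view A [view_spec()].
#' @return Numeric vector of length `view$width`; entries are 0/1 for
#'   boolean views and nonnegative integers for count views.
#' @export
featurize_smiles <- function(smiles, view = view_spec("avalon")) {
  if (length(smiles) != 1L || !is.character(smiles)) {
    stop_cffat("smiles must be a single string")
  }
  res <- run_fingerprinter(smiles, view)
  if (res$ok[1] != 1L) stop_cffat("unparseable SMILES: %s", smiles)
  decode_bits(res$bits[1], view$width)
}

#' Fingerprint a vector of SMILES strings
#'
#' In strict mode (default) any unparseable SMILES aborts with an error
#' listing the offending rows. In lenient mode failing rows are dropped and
#' reported through the `dropped` attribute of the result.
#'
#' @param smiles_list Character vector of SMILES.
#' @param view A [view_spec()].
#' @param strict Abort on any invalid SMILES (default) or drop them.
#' @return Numeric matrix `n x width` (n excludes dropped rows in lenient
#'   mode), with attribute `dropped` holding the dropped row indices.
#' @export
featurize_table <- function(smiles_list, view = view_spec("avalon"),
                            strict = TRUE) {
  if (!length(smiles_list)) stop_cffat("smiles_list is empty")
  res <- run_fingerprinter(as.character(smiles_list), view)
  bad <- which(res$ok != 1L)
  if (length(bad) && strict) {
    stop_cffat("unparseable SMILES at row(s) %s: %s",
               paste(bad, collapse = ", "),
               paste(smiles_list[bad], collapse = ", "))
  }
  keep <- setdiff(seq_along(smiles_list), bad)
  if (!length(keep)) stop_cffat("no valid SMILES remained")
  M <- t(vapply(keep, function(i) decode_bits(res$bits[i], view$width),
                numeric(view$width)))
  if (length(bad)) {
    message(sprintf("featurize_table: dropped %d unparseable row(s): %s",
                    length(bad), paste(bad, collapse = ", ")))
  }
  attr(M, "dropped") <- bad
  M
}

#' Endpoint prior-knowledge vector
#'
#' The (x, y, z) triple of species, administration-route and toxicity-type
#' codes that identifies an endpoint; appended to every sample of that
#' endpoint as three extra raw-integer columns.
#'
#' @param x Species code in 1..15.
#' @param y Route code in 1..8.
#' @param z Toxicity-type code in 1..3.
#' @return A `prior_knowledge` object.
#' @export
prior_knowledge <- function(x, y, z) {
  m <- endpoint_meta(1L, x, y, z)  # reuses the range checks
  structure(list(x = m$species_code, y = m$route_code, z = m$toxtype_code),
            class = "prior_knowledge")
}

#' Append an endpoint's prior-knowledge vector to a feature matrix
#'
#' Trees are scale-invariant, so the codes are appended un-normalised.
#'
#' @param X Numeric matrix `n x d`.
#' @param pk A [prior_knowledge()] (or an [endpoint_meta()], from which the
#'   triple is taken).
#' @return Matrix `n x (d + 3)`; the first `d` columns are unchanged and
#'   the trailing columns are constant at (x, y, z).
#' @export
append_prior_knowledge <- function(X, pk) {
  check_matrix(X, "X")
  if (inherits(pk, "endpoint_meta")) {
    pk <- prior_knowledge(pk$species_code, pk$route_code, pk$toxtype_code)
  }
  if (!inherits(pk, "prior_knowledge")) {
    stop_cffat("pk must be a prior_knowledge or endpoint_meta object")
  }
  n <- nrow(X)
  out <- cbind(X, pk_x = rep(pk$x, n), pk_y = rep(pk$y, n), pk_z = rep(pk$z, n))
  out
}
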