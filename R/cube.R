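#' Construct an omics layer
#'
#' A light container for one genes x samples data matrix of a given kind.
#' Gene and sample identifiers must be unique; they are taken from the matrix
#' dimnames unless given explicitly.
#'
#' @param values genes x samples numeric matrix.
#' @param kind one of \code{"expression"}, \code{"copy_number"}, \code{"mutation"}.
#' @param name short label used for the cube's layer names (defaults to an
#'   abbreviation of the kind: GE, CN or MT).
#' @param gene_ids,sample_ids identifier vectors; default to the dimnames.
#' @return An object of class \code{"omics_layer"}.
#' @export
omics_layer <- function(values, kind = c("expression", "copy_number", "mutation"),
                        name = NULL, gene_ids = rownames(values),
                        sample_ids = colnames(values)) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("omics_layer: gene and sample identifiers are required")
  if (anyDuplicated(gene_ids)) stop("omics_layer: duplicated gene identifiers")
  if (anyDuplicated(sample_ids)) stop("omics_layer: duplicated sample identifiers")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("omics_layer: identifier lengths do not match the matrix")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (is.null(name)) name <- switch(kind, expression = "GE", copy_number = "CN",
                                    mutation = "MT")
  if (kind == "mutation" && !all(values %in% c(0, 1)))
    stop("omics_layer: mutation values must be 0/1")
  structure(list(name = name, kind = kind, values = values,
                 gene_ids = gene_ids, sample_ids = sample_ids,
                 flags = list()),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("omics_layer '%s' (%s): %d genes x %d samples\n",
              x$name, x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Standardize a gene-expression layer per gene
#'
#' Mean-centres and scales each gene row to unit standard deviation. By
#' default the statistics are computed from the layer itself; an independent
#' cohort (e.g. a xenograft panel standardized with its own cohort-internal
#' statistics) can pass precomputed per-gene means and SDs instead.
#'
#' @param layer an \code{omics_layer} of kind \code{"expression"}.
#' @param ref_means,ref_sds optional named per-gene statistics; names must
#'   match the layer's gene identifiers in order.
#' @param sd_type \code{"population"} (divide by n; default, so small worked
#'   examples are deterministic) or \code{"sample"} (divide by n-1).
#' @return The standardized layer. Genes with zero variance become all-zero
#'   rows and are recorded in \code{$flags$zero_variance_genes}.
#' @export
standardize_expression <- function(layer, ref_means = NULL, ref_sds = NULL,
                                   sd_type = c("population", "sample")) {
  stopifnot(inherits(layer, "omics_layer"))
  if (layer$kind != "expression")
    stop("standardize_expression: layer kind must be 'expression'")
  sd_type <- match.arg(sd_type)
  x <- layer$values
  n <- ncol(x)
  if (is.null(ref_means) != is.null(ref_sds))
    stop("standardize_expression: supply both ref_means and ref_sds or neither")
  if (is.null(ref_means)) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    if (sd_type == "sample") v <- v * n / (n - 1)
    sg <- sqrt(v)
  } else {
    if (!is.null(names(ref_means)) && !identical(names(ref_means), layer$gene_ids))
      stop("standardize_expression: reference statistics are not aligned to the layer's genes")
    if (length(ref_means) != nrow(x) || length(ref_sds) != nrow(x))
      stop("standardize_expression: reference statistics are not aligned to the layer's genes")
    mu <- as.numeric(ref_means); sg <- as.numeric(ref_sds)
  }
  zero <- sg <= 0 | !is.finite(sg)
  z <- (x - mu) / ifelse(zero, 1, sg)
  z[zero, ] <- 0
  layer$values <- z
  layer$flags$zero_variance_genes <- layer$gene_ids[zero]
  layer
}

#' Ternarize a copy-number layer into loss / neutral / gain
#'
#' Maps raw copy number to -1 (loss) when \code{cn <= loss_threshold}, 1 (gain)
#' when \code{cn > gain_threshold} (strict), 0 otherwise.
#'
#' @param layer an \code{omics_layer} of kind \code{"copy_number"}.
#' @param gain_threshold gain calls require copy number strictly above this
#'   value (default 5).
#' @param loss_threshold loss calls require copy number at or below this value
#'   (default 1).
#' @return The layer with values in \{-1, 0, 1\}.
#' @export
ternarize_copy_number <- function(layer, gain_threshold = 5, loss_threshold = 1) {
  stopifnot(inherits(layer, "omics_layer"))
  if (layer$kind != "copy_number")
    stop("ternarize_copy_number: layer kind must be 'copy_number'")
  x <- layer$values
  if (any(x < 0)) stop("ternarize_copy_number: negative raw copy number")
  layer$values <- ifelse(x > gain_threshold, 1, ifelse(x <= loss_threshold, -1, 0))
  layer
}

#' Split a mixed-sign layer into positive- and negative-part layers
#'
#' Applied after standardization (expression) or ternarization (copy number):
#' each entry x becomes \code{max(x, 0)} in the "(+)" layer and \code{max(-x, 0)}
#' in the "(-)" layer, so plus minus minus reconstructs x exactly.
#'
#' @param layer an expression or copy-number \code{omics_layer}.
#' @return A list of two layers named \code{plus} and \code{minus}.
#' @export
sign_split <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  if (!layer$kind %in% c("expression", "copy_number"))
    stop("sign_split: only expression and copy-number layers carry mixed signs")
  plus <- layer; minus <- layer
  plus$values <- pmax(layer$values, 0)
  minus$values <- pmax(-layer$values, 0)
  plus$name <- paste0(layer$name, "(+)")
  minus$name <- paste0(layer$name, "(-)")
  list(plus = plus, minus = minus)
}

#' Stack aligned omics layers into a non-negative data cube
#'
#' Restricts all layers to the intersection of their gene and sample
#' identifiers (optionally further restricted to a gene panel), reorders each
#' to a common ordering, and stacks them into a genes x samples x layers
#' array. Layer order is the order given by the caller.
#'
#' @param layers list of \code{omics_layer}s with non-negative values
#'   (run [sign_split()] first for mixed-sign kinds).
#' @param gene_subset optional identifier vector (e.g. a cancer gene panel).
#' @return An object of class \code{"data_cube"}: list with \code{values}
#'   (3-way array with dimnames), \code{gene_ids}, \code{sample_ids},
#'   \code{layer_names} and an \code{alignment} report of dropped identifiers.
#' @export
build_cube <- function(layers, gene_subset = NULL) {
  stopifnot(length(layers) >= 1, all(vapply(layers, inherits, TRUE, "omics_layer")))
  genes <- Reduce(intersect, lapply(layers, `[[`, "gene_ids"))
  samples <- Reduce(intersect, lapply(layers, `[[`, "sample_ids"))
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) == 0 || length(samples) == 0)
    stop("build_cube: empty gene or sample intersection across layers")
  genes <- sort(genes); samples <- sort(samples)
  layer_names <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(layer_names)) stop("build_cube: duplicated layer names")
  a <- array(0, dim = c(length(genes), length(samples), length(layers)),
             dimnames = list(genes, samples, layer_names))
  for (i in seq_along(layers)) {
    v <- layers[[i]]$values[genes, samples, drop = FALSE]
    if (any(v < 0)) stop("build_cube: layer '", layer_names[i],
                         "' has negative entries; sign_split mixed-sign layers first")
    a[, , i] <- v
  }
  dropped <- list(
    genes = lapply(layers, function(l) setdiff(l$gene_ids, genes)),
    samples = lapply(layers, function(l) setdiff(l$sample_ids, samples)))
  names(dropped$genes) <- names(dropped$samples) <- layer_names
  structure(list(values = a, gene_ids = genes, sample_ids = samples,
                 layer_names = layer_names, alignment = dropped),
            class = "data_cube")
}

#' Wrap a non-negative 3-way array as a data cube
#'
#' Convenience constructor used by the simulators and tests.
#'
#' @param values genes x samples x layers non-negative array.
#' @param gene_ids,sample_ids,layer_names identifier vectors; defaults are
#'   generated.
#' @return A \code{"data_cube"}.
#' @export
as_data_cube <- function(values,
                         gene_ids = paste0("g", seq_len(dim(values)[1])),
                         sample_ids = paste0("s", seq_len(dim(values)[2])),
                         layer_names = paste0("L", seq_len(dim(values)[3]))) {
  stopifnot(length(dim(values)) == 3)
  if (any(values < 0)) stop("as_data_cube: entries must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids, layer_names)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 layer_names = layer_names, alignment = NULL),
            class = "data_cube")
}

## Accept either a data_cube or a bare array everywhere internally.
cube_values <- function(x) {
  if (inherits(x, "data_cube")) x$values
  else if (is.array(x) && length(dim(x)) == 3) x
  else stop("expected a data_cube or a 3-way array")
}

#' @export
print.data_cube <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("data_cube: %d genes x %d samples x %d layers (%s)\n",
              dm[1], dm[2], dm[3], paste(x$layer_names, collapse = ", ")))
  invisible(x)
}

#' Per-layer weights balancing the data types
#'
#' Each layer slab receives the constant weight 1 / ||X_d||_F^2 (the inverse of
#' its squared Frobenius norm), so data types with less overall variance obtain
#' high weights and are not dominated by high-variance types such as expression.
#'
#' @param cube a \code{data_cube} or 3-way array.
#' @param layer_weights optional override: one non-negative scalar per layer.
#' @return An object of class \code{"weight_tensor"}: list with \code{values}
#'   (array of the cube's shape) and \code{layer_weights}.
#' @export
compute_weights <- function(cube, layer_weights = NULL) {
  a <- cube_values(cube)
  d <- dim(a)[3]
  if (is.null(layer_weights)) {
    sq <- vapply(seq_len(d), function(i) sum(a[, , i]^2), 0)
    if (any(sq == 0)) stop("compute_weights: all-zero layer slab (degenerate layer)")
    layer_weights <- 1 / sq
  } else {
    if (length(layer_weights) != d || any(layer_weights < 0))
      stop("compute_weights: need one non-negative weight per layer")
  }
  w <- array(rep(layer_weights, each = dim(a)[1] * dim(a)[2]), dim = dim(a))
  structure(list(values = w, layer_weights = layer_weights),
            class = "weight_tensor")
}

weight_values <- function(w, cube = NULL) {
  if (is.null(w)) {
    if (is.null(cube)) stop("need a cube to build unit weights")
    array(1, dim = dim(cube_values(cube)))
  } else if (inherits(w, "weight_tensor")) w$values
  else if (is.array(w) && length(dim(w)) == 3) w
  else stop("expected a weight_tensor or a 3-way array")
}

#' Read a genes x samples TSV matrix
#'
#' First column gene identifiers, header row sample identifiers.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_omics_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a genes x samples matrix as TSV
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @export
write_omics_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
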