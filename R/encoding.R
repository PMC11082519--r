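#' Recode a SNP matrix to major/minor alleles
#'
#' Per row (SNP), the more frequent allele among non-missing entries is
#' recoded to 0 and the rarer one to 1; exact ties leave the row's coding
#' unchanged, and monomorphic rows come out all-0. The operation is
#' idempotent and commutes with column permutation.
#'
#' @param m Integer matrix (loci x haplotype columns) with values 0/1 and
#'   NA for missing; a `hap_matrix` is accepted.
#' @return Matrix of the same shape, values 0 (major), 1 (minor), NA.
#' @export
#' @examples
#' to_major_minor(matrix(c(1, 1, 1, 0), 1))
to_major_minor <- function(m) {
  stopifnot(is.matrix(m))
  x <- unclass(m)
  ones <- rowSums(x == 1, na.rm = TRUE)
  zeros <- rowSums(x == 0, na.rm = TRUE)
  flip <- ones > zeros
  if (any(flip)) x[flip, ] <- 1L - x[flip, , drop = FALSE]
  attributes(x) <- attributes(m)[c("dim", "dimnames", "pop_partition", "class")]
  x
}

#' Inject missing genotypes at a fixed rate
#'
#' Independently replaces each entry by NA with the given probability,
#' emulating the missing-data fraction of the empirical SNP matrix (4.4\%
#' by default) so that the classifier trains on images with the same
#' missingness structure it will see at prediction time.
#'
#' @param image Numeric/integer matrix (already recoded or not).
#' @param rate Per-entry missing probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The matrix with missing entries set to NA.
#' @export
inject_missing <- function(image, rate = 0.044, seed = NULL) {
  stopifnot(is.matrix(image))
  if (rate < 0 || rate >= 1) abort("`rate` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(image)
  mask <- runif(length(image)) < rate
  image[matrix(mask, nrow(image))] <- NA
  image
}

# pack an encoded image (loci x samples, 0/1/NA) into the byte layout the
# network consumes: one column per image, channel-major (sample fastest)
encode_raw <- function(m) {
  v <- as.integer(t(unclass(m)))
  v[is.na(v)] <- 2L
  as.raw(v)
}

#' Assemble encoded images into a training batch
#'
#' Recodes each matrix to major/minor alleles, injects missing data,
#' reshuffles the image order, and assigns the first `ceiling(val_frac *
#' N)` images (after shuffling) to the validation set and the rest to
#' training.
#'
#' @param matrices List of haplotype/SNP matrices of identical shape.
#' @param labels Scenario label per matrix (character, one of
#'   [scenarios()]), or NA for unlabeled images.
#' @param draws Optional list of `parameter_draw` objects (or a tibble)
#'   aligned with `matrices`.
#' @param val_frac Validation fraction (default 0.25).
#' @param missing_rate Missing-injection rate applied after recoding
#'   (default 0.044); use 0 for matrices that already contain missing
#'   entries.
#' @param seed Optional integer seed.
#' @return A `sim_batch`: raw-byte image store plus `labels`, `draws`,
#'   `split`.
#' @export
assemble_batch <- function(matrices, labels, draws = NULL, val_frac = 0.25,
                           missing_rate = 0.044, seed = NULL) {
  n <- length(matrices)
  stopifnot(n > 0, length(labels) == n)
  if (!is.null(draws) && !is.data.frame(draws) && length(draws) != n)
    abort("`draws` must align with `matrices`")
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(matrices[[1]])
  images <- matrix(as.raw(0), nrow = prod(dims), ncol = n)
  for (i in seq_len(n)) {
    m <- matrices[[i]]
    if (!all(dim(m) == dims)) abort("all matrices must have equal shape")
    m <- to_major_minor(m)
    if (missing_rate > 0) m <- inject_missing(m, missing_rate)
    images[, i] <- encode_raw(m)
  }
  if (is.data.frame(draws)) {
    draws_tbl <- tibble::as_tibble(draws)
  } else if (!is.null(draws)) {
    draws_tbl <- dplyr::bind_rows(lapply(draws, tidy))
  } else {
    draws_tbl <- NULL
  }
  perm <- sample.int(n)
  n_val <- ceiling(val_frac * n)
  split <- c(rep("validation", n_val), rep("train", n - n_val))
  structure(list(
    images = images[, perm, drop = FALSE],
    n_loci = dims[1], n_samples = dims[2],
    labels = as.character(labels)[perm],
    draws = if (!is.null(draws_tbl)) draws_tbl[perm, , drop = FALSE],
    split = split
  ), class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  cat("<sim_batch>", ncol(x$images), "images of", x$n_loci, "x",
      x$n_samples, "|", sum(x$split == "train"), "train /",
      sum(x$split == "validation"), "validation\n")
  if (!all(is.na(x$labels)))
    print(table(x$labels, x$split))
  invisible(x)
}

# subset helper: raw image columns for one part of the batch
batch_images <- function(batch, part = c("train", "validation", "all")) {
  part <- match.arg(part)
  idx <- if (part == "all") seq_along(batch$split)
         else which(batch$split == part)
  list(images = batch$images[, idx, drop = FALSE],
       labels = batch$labels[idx], idx = idx)
}

#' Random SNP subsamples of an empirical matrix
#'
#' Draws `reps` independent subsets of `n_snps` rows (without replacement
#' within a replicate) from a phased SNP matrix and recodes each to
#' major/minor alleles. No missing data are injected: empirical matrices
#' carry their own missingness.
#'
#' @param matrix A haplotype matrix with at least `n_snps` rows.
#' @param n_snps SNPs per replicate (default 1000).
#' @param reps Number of replicates (default 100).
#' @param seed Optional integer seed.
#' @return List of `reps` encoded matrices (`n_snps` x samples).
#' @export
subsample_empirical <- function(matrix, n_snps = 1000, reps = 100,
                                seed = NULL) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < n_snps)
    abort("matrix has fewer rows than `n_snps`")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(i) {
    rows <- sample.int(nrow(matrix), n_snps)
    to_major_minor(unclass(matrix)[rows, , drop = FALSE])
  })
}
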