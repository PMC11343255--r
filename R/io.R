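# File interfaces: cohort TSV + schema sidecar, variant TSV, GMT gene sets,
# pLI/devDEG TSV, model JSON serialisation, and a minimal VCF reader that
# maps GENE/CSQ-style INFO keys into the variant-table schema.

#' Write / read a phenotype cohort as TSV with a schema sidecar
#'
#' The data file is plain TSV with a header; the sidecar (same path with
#' `.schema.tsv` appended) holds the typed schema (`name`, `type`,
#' `n_levels`, `category`).
#'
#' @param cohort a [phenotype_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(cohort$schema), paste0(path, ".schema.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  dat <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  sch <- utils::read.table(paste0(path, ".schema.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  class(sch) <- c("feature_schema", "data.frame")
  validate_schema(sch)
  phenotype_cohort(dat, sch)
}

#' Write / read a variant table as TSV
#'
#' @param variants a variant table data.frame.
#' @param path file path.
#' @return `path` invisibly / the table.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("individual_id", "gene", "origin", "consequence")
  miss <- setdiff(needed, names(v))
  if (length(miss)) stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  class(v) <- c("variant_table", "data.frame")
  v
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene IDs.
#'
#' @param gene_sets named list of character vectors.
#' @param path file path.
#' @return `path` invisibly / a named list.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' Write / read gene annotations (pLI + sets + devDEG)
#'
#' pLI goes to `<stem>_pli.tsv`, gene sets to `<stem>_sets.gmt`, devDEG
#' memberships to `<stem>_devdeg.gmt`.
#'
#' @param ann a `gene_annotations` object.
#' @param stem path stem.
#' @return `stem` invisibly / a `gene_annotations` object.
#' @export
write_annotations <- function(ann, stem) {
  utils::write.table(ann$pli, paste0(stem, "_pli.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(ann$gene_sets, paste0(stem, "_sets.gmt"))
  write_gmt(ann$devdeg, paste0(stem, "_devdeg.gmt"))
  invisible(stem)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(stem) {
  pli <- utils::read.table(paste0(stem, "_pli.tsv"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(pli$gene)) stop("integrity error: duplicate gene IDs")
  structure(list(pli = pli,
                 gene_sets = read_gmt(paste0(stem, "_sets.gmt")),
                 devdeg = read_gmt(paste0(stem, "_devdeg.gmt"))),
            class = "gene_annotations")
}

#' Serialise / restore a fitted GFMM as versioned JSON
#'
#' Stores the schema, all parameters, the winning chain seed, and fit
#' metadata; reload reproduces predictions exactly.
#'
#' @param fit a [gfmm_fit()] result.
#' @param path JSON path.
#' @return `path` invisibly / a `gfmm_fit` (without responsibilities).
#' @export
write_model_json <- function(fit, path) {
  obj <- list(
    format = "mixphen-gfmm", version = 1L,
    K = fit$K, n = fit$n, ll = fit$ll, n_parameters = fit$n_parameters,
    converged = fit$converged, seed = fit$seed,
    schema = as.data.frame(fit$schema),
    prior_coef = fit$params$prior_coef,
    mean = fit$params$mean, sd = fit$params$sd, p = fit$params$p,
    cat = fit$params$cat
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mixphen-gfmm")) stop("not a serialized GFMM model")
  sch <- obj$schema
  class(sch) <- c("feature_schema", "data.frame")
  params <- empty_params(obj$K, sch)
  params$prior_coef <- matrix(unlist(obj$prior_coef), 3, obj$K,
                              dimnames = list(c("intercept", "sex", "age"), NULL))
  as_mat <- function(x, nr) matrix(unlist(x), nrow = nr)
  if (length(params$j_cont)) {
    params$mean <- as_mat(obj$mean, obj$K)
    params$sd <- as_mat(obj$sd, obj$K)
  }
  if (length(params$j_bin)) params$p <- as_mat(obj$p, obj$K)
  if (length(params$j_cat)) {
    if (is.array(obj$cat) && length(dim(obj$cat)) == 3) {
      params$cat <- lapply(seq_len(dim(obj$cat)[1]), function(i) {
        matrix(obj$cat[i, , ], dim(obj$cat)[2], dim(obj$cat)[3])
      })
    } else {
      params$cat <- lapply(obj$cat, function(m) as_mat(m, obj$K))
    }
  }
  structure(list(params = params, responsibilities = NULL, labels = NULL,
                 ll = obj$ll, ll_trace = NULL, n_parameters = obj$n_parameters,
                 converged = obj$converged, seed = obj$seed, K = obj$K,
                 n = obj$n, schema = sch), class = "gfmm_fit")
}

#' Minimal VCF reader mapping into the variant-table schema
#'
#' Reads an uncompressed, single-sample-per-record VCF-like file
#' (1-based coordinates) and maps INFO keys into variant-table columns:
#' `GENE` -> gene, `CSQ` -> consequence, `LOF` -> lof_confidence,
#' `AM` -> missense_class, `AF` -> allele_frequency, `ORIGIN` -> origin,
#' `IND`/`FAM` -> individual/family IDs.  Intended for the narrow
#' annotated-call interchange format; it is not a general-purpose VCF
#' parser.
#'
#' @param path VCF path.
#' @return A variant table data.frame with a `variant_key` of
#'   `chrom:pos:ref:alt`.
#' @export
read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(individual_id = character(), family_id = character(),
                      gene = character(), origin = character(),
                      consequence = character(), lof_confidence = character(),
                      missense_class = character(), allele_frequency = numeric(),
                      variant_key = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (pair in kv) if (pair[1] == key && length(pair) == 2) return(pair[2])
    NA_character_
  }
  rows <- lapply(fields, function(f) {
    if (length(f) < 8) stop("malformed VCF record: fewer than 8 fields")
    info <- f[8]
    af <- info_get(info, "AF")
    data.frame(
      individual_id = info_get(info, "IND"),
      family_id = info_get(info, "FAM"),
      gene = info_get(info, "GENE"),
      origin = info_get(info, "ORIGIN"),
      consequence = info_get(info, "CSQ"),
      lof_confidence = info_get(info, "LOF"),
      missense_class = info_get(info, "AM"),
      allele_frequency = if (is.na(af)) NA_real_ else as.numeric(af),
      variant_key = paste(f[1], f[2], f[4], f[5], sep = ":"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_table", "data.frame")
  out
}
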