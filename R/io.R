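#' Read a papillae patch table
#'
#' Tab-separated with header; expects at least `query_gene`, `bait_gene`,
#' `assay`, `patch_index`, `papillae_count`, `grew` (and optionally
#' `strain_id`, `lawn`).
#'
#' @param path File path.
#' @return Tibble of patch records.
#' @export
read_patch_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("query_gene", "bait_gene", "assay", "patch_index",
              "papillae_count", "grew")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols) > 0) {
    stop("patch table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read gene sets in GMT format
#'
#' One module per line: name, annotation/description, then member genes,
#' tab-separated.
#'
#' @param path File path.
#' @return Tibble with columns `module`, `annotation`, `gene` (one row per
#'   member gene).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map_dfr(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line (need name, annotation, >= 1 gene): ",
           substr(ln, 1, 60), call. = FALSE)
    }
    tibble::tibble(module = fields[1], annotation = fields[2],
                   gene = fields[-(1:2)])
  })
}

#' Read a plain gene list (one gene per line)
#'
#' @param path File path.
#' @return Character vector of genes; blank lines and `#` comments are
#'   dropped.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# Standard MAF variant classification -> internal class labels
maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Ins = "frameshift_insertion",
  Frame_Shift_Del = "frameshift_deletion",
  In_Frame_Ins = "inframe_insertion",
  In_Frame_Del = "inframe_deletion",
  Splice_Site = "splice_site",
  Silent = "silent"
)

#' Read a MAF-like mutation table
#'
#' Accepts either the package's own column names (`sample`, `gene`,
#' `variant_class`) or standard MAF names (`Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `Variant_Classification`), mapping the standard MAF
#' variant classifications onto the internal labels; unrecognised classes
#' become `"other"`. Optional columns `ndamage` and
#' `in_mononucleotide_repeat` are preserved (and default to `NA` / `FALSE`
#' when absent).
#'
#' @param path File path (TSV with header).
#' @return Tibble with columns `sample`, `gene`, `variant_class`,
#'   `ndamage`, `in_mononucleotide_repeat`.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  rename_if <- function(df, from, to) {
    if (from %in% names(df) && !to %in% names(df)) {
      names(df)[names(df) == from] <- to
    }
    df
  }
  raw <- raw |>
    rename_if("Tumor_Sample_Barcode", "sample") |>
    rename_if("Hugo_Symbol", "gene") |>
    rename_if("Variant_Classification", "variant_class")
  missing_cols <- setdiff(c("sample", "gene", "variant_class"), names(raw))
  if (length(missing_cols) > 0) {
    stop("MAF ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  mapped <- unname(maf_class_map[raw$variant_class])
  raw$variant_class <- ifelse(
    is.na(mapped),
    ifelse(raw$variant_class %in% unname(maf_class_map), raw$variant_class,
           "other"),
    mapped
  )
  if (!"ndamage" %in% names(raw)) raw$ndamage <- NA_integer_
  if (!"in_mononucleotide_repeat" %in% names(raw)) {
    raw$in_mononucleotide_repeat <- FALSE
  }
  dplyr::select(raw, "sample", "gene", "variant_class", "ndamage",
                "in_mononucleotide_repeat")
}

#' Read a samples-by-genes matrix TSV into long format
#'
#' The first column must identify the sample; remaining columns are genes.
#'
#' @param path File path.
#' @param value_name Name for the value column (e.g. `"gistic"`, `"z"`,
#'   `"hypermethylated"`).
#' @return Long tibble with columns `sample`, `gene`, and `value_name`.
#' @export
read_matrix_tsv <- function(path, value_name = "value") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  names(wide)[1] <- "sample"
  tidyr::pivot_longer(wide, -"sample", names_to = "gene",
                      values_to = value_name)
}
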