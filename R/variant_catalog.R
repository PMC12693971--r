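CATALOG_COLS <- c("gene", "chrom", "pos", "ref", "archaic", "status")
VALID_CHROMS <- c(as.character(1:22), "X")
VALID_STATUS <- c("fixed_af1", "high_frequency")

validate_catalog <- function(df, what = "catalog") {
  assert_columns(df, CATALOG_COLS, what)
  df$chrom <- as.character(df$chrom)
  df$gene <- as.character(df$gene)
  df$ref <- toupper(as.character(df$ref))
  df$archaic <- toupper(as.character(df$archaic))
  df$pos <- as.integer(df$pos)
  bad <- !df$chrom %in% VALID_CHROMS
  if (any(bad)) stopf("invalid chromosome label(s): %s",
                      paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(is.na(df$pos) | df$pos <= 0)) {
    stopf("positions must be positive 1-based hg38 coordinates")
  }
  bases <- c("A", "C", "G", "T")
  bad <- !df$ref %in% bases | !df$archaic %in% bases
  if (any(bad)) {
    stopf("malformed allele at %s: alleles must be single bases A/C/G/T",
          paste(site_key(df$chrom[bad], df$pos[bad]), collapse = ", "))
  }
  same <- df$ref == df$archaic
  if (any(same)) {
    stopf("reference and archaic allele identical at %s",
          paste(site_key(df$chrom[same], df$pos[same]), collapse = ", "))
  }
  if (any(!df$status %in% VALID_STATUS)) {
    stopf("`status` must be one of: %s", paste(VALID_STATUS, collapse = ", "))
  }
  key <- site_key(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    stopf("duplicate catalog site(s): %s",
          paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("asnv_catalog", "data.frame")
  df
}

#' Load an aSNV variant catalog
#'
#' Reads a tab- or comma-separated catalog of archaic single-nucleotide
#' variant sites and validates it. Required columns: `gene`, `chrom`
#' (1--22 or X), `pos_hg38` (1-based hg38 position), `ref`, `archaic`
#' (single bases, distinct), `status` (`fixed_af1` or `high_frequency`).
#' Duplicate chromosome+position entries are rejected.
#'
#' @param path Path to the catalog file. Comma separation is assumed for
#'   `.csv`, tab separation otherwise.
#' @return A validated `asnv_catalog` data frame with columns `gene`,
#'   `chrom`, `pos`, `ref`, `archaic`, `status`.
#' @examples
#' cat42 <- load_catalog(system.file("extdata", "catalog42_synthetic.tsv",
#'                                   package = "asnvkit"))
#' nrow(cat42)  # 42
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  df <- reader(path, stringsAsFactors = FALSE)
  if ("pos_hg38" %in% names(df) && !"pos" %in% names(df)) {
    names(df)[names(df) == "pos_hg38"] <- "pos"
  }
  validate_catalog(df, what = sprintf("catalog file '%s'", basename(path)))
}

#' Curate an aSNV catalog
#'
#' Applies exclusion and inclusion rules to a loaded catalog: sites named
#' in `exclusions` are removed (each with a recorded reason), and the
#' `inclusions` rows are appended. An exclusion rule that references a
#' position absent from the catalog raises a warning, not an error.
#' Curation is idempotent: applying the same rules to an already-curated
#' catalog changes nothing.
#'
#' @param catalog An `asnv_catalog` data frame (see [load_catalog()]).
#' @param exclusions Data frame with columns `chrom`, `pos`, `reason`
#'   (one of `non_exonic`, `ambiguous_liftover`, `non_pass_filter`), or
#'   `NULL` for none.
#' @param inclusions Data frame of full catalog rows to append (same
#'   columns as the catalog), or `NULL`.
#' @return A list with `retained` (curated `asnv_catalog`), `log` (one
#'   row per removed site with its reason), and `n_genes` (count of
#'   distinct gene symbols among retained sites).
#' @examples
#' cat42 <- build_fixture("catalog42")$catalog
#' cur <- curate_catalog(cat42, default_exclusions(), tktl1_site())
#' nrow(cur$retained)  # 39
#' cur$n_genes         # 33
#' @export
curate_catalog <- function(catalog, exclusions = NULL, inclusions = NULL) {
  catalog <- validate_catalog(as.data.frame(catalog))
  log <- data.frame(gene = character(), chrom = character(),
                    pos = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  retained <- catalog
  if (!is.null(exclusions) && nrow(exclusions)) {
    assert_columns(exclusions, c("chrom", "pos", "reason"), "`exclusions`")
    exkey <- site_key(as.character(exclusions$chrom), exclusions$pos)
    key <- site_key(retained$chrom, retained$pos)
    absent <- !exkey %in% key
    if (any(absent)) {
      warnf("exclusion rule(s) reference position(s) absent from the catalog: %s",
            paste(exkey[absent], collapse = ", "))
    }
    hit <- key %in% exkey
    if (any(hit)) {
      dropped <- retained[hit, , drop = FALSE]
      dropped$reason <- exclusions$reason[match(site_key(dropped$chrom, dropped$pos),
                                                exkey)]
      log <- rbind(log, dropped[, c("gene", "chrom", "pos", "reason")])
      retained <- retained[!hit, , drop = FALSE]
    }
  }
  if (!is.null(inclusions) && nrow(inclusions)) {
    inc <- validate_catalog(as.data.frame(inclusions), what = "`inclusions`")
    new <- !site_key(inc$chrom, inc$pos) %in% site_key(retained$chrom, retained$pos)
    retained <- rbind(as.data.frame(retained), as.data.frame(inc[new, , drop = FALSE]))
  }
  retained <- validate_catalog(retained)
  rownames(log) <- NULL
  list(retained = retained, log = log,
       n_genes = length(unique(retained$gene)))
}

#' Printed exclusion rules for the 42-site catalog
#'
#' Exclusions applied during catalog curation: three sites outside
#' translated exons (in C1orf159, DNHD1 and DNMT3L) and one site with an
#' ambiguous hg38 liftover (TBC1D3).
#'
#' @return Data frame with columns `chrom`, `pos`, `reason`.
#' @export
default_exclusions <- function() {
  data.frame(
    chrom = c("1", "11", "21", "17"),
    pos = c(1091245L, 6534188L, 44251169L, 38202786L),
    reason = c("non_exonic", "non_exonic", "non_exonic",
               "ambiguous_liftover"),
    stringsAsFactors = FALSE
  )
}

#' The TKTL1 high-frequency aSNV site
#'
#' The chrX:154315258 G>A missense variant in TKTL1 (rs111811311), a
#' human-specific high-frequency (not fully fixed) change added to the
#' analysis catalog because of its reported effects on cortical
#' neurogenesis in model systems.
#'
#' @return A one-row catalog data frame.
#' @export
tktl1_site <- function() {
  data.frame(gene = "TKTL1", chrom = "X", pos = 154315258L,
             ref = "G", archaic = "A", status = "high_frequency",
             stringsAsFactors = FALSE)
}

#' Exclusion rule for the single non-PASS catalog site
#'
#' The chr9:6606647 site fails the upstream variant-level FILTER and is
#' dropped from the queryable set.
#'
#' @return Data frame with columns `chrom`, `pos`, `reason`.
#' @export
non_pass_exclusion <- function() {
  data.frame(chrom = "9", pos = 6606647L, reason = "non_pass_filter",
             stringsAsFactors = FALSE)
}
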