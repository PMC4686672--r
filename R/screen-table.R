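#' Load the packaged RNAi lifespan-screen table
#'
#' Returns the packaged cross-tabulation of the 41 candidate genes screened by
#' individual RNAi in *C. elegans*: each gene's regulation direction during
#' ageing (up- or downregulated) and its lifespan-effect category.
#'
#' @return A tibble with columns `gene`, `regulation`
#'   (`"upregulated"`/`"downregulated"`) and `category` (one of `"Shortened"`,
#'   `"Unchanged"`, `"Extended<5%"`, `"Extended>=5%"`), 41 rows.
#' @export
#' @examples
#' tab <- load_screen_table()
#' table(tab$regulation)
load_screen_table <- function() {
  path <- system.file("extdata", "screen_table.tsv", package = "agecourse",
                      mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  stopifnot(!anyDuplicated(tab$gene),
            all(tab$category %in% .screen_categories),
            all(tab$regulation %in% c("upregulated", "downregulated")))
  tab
}
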