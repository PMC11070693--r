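#' Build a validated mixed-type data table
#'
#' Bundles a sample-by-variable data frame with its variable specification
#' (type and contextual flag per column).  Continuous columns must be
#' numeric; categorical columns are stored as character and must show at
#' least two observed levels.  Missing values are `NA`.
#'
#' @param df data.frame of samples (rows) by variables (columns).
#' @param specs data.frame with columns `name`, `vtype`
#'   (`"continuous"`/`"categorical"`) and `is_contextual` (logical).  If
#'   omitted, numeric columns are declared continuous and the rest
#'   categorical, none contextual.
#' @return an object of class `mindnet_data`.
#' @export
mindnet_data <- function(df, specs = NULL) {
  stopifnot(is.data.frame(df))
  if (nrow(df) < 2L || ncol(df) < 2L) stop("need N >= 2 samples and P >= 2 variables")
  if (is.null(specs)) {
    specs <- data.frame(
      name = names(df),
      vtype = ifelse(vapply(df, is.numeric, logical(1)), "continuous", "categorical"),
      is_contextual = FALSE,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "vtype", "is_contextual") %in% names(specs)))
  if (anyDuplicated(specs$name)) stop("variable names must be unique")
  missing_cols <- setdiff(specs$name, names(df))
  if (length(missing_cols)) {
    stop("spec lists column(s) absent from the table: ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), specs$name)
  if (length(extra)) stop("unknown column(s) in table: ", paste(extra, collapse = ", "))
  df <- df[specs$name]
  levels <- vector("list", nrow(specs))
  names(levels) <- specs$name
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    if (specs$vtype[i] == "continuous") {
      if (!is.numeric(df[[nm]])) {
        suppressWarnings(conv <- as.numeric(as.character(df[[nm]])))
        bad <- which(!is.na(as.character(df[[nm]])) & is.na(conv))
        if (length(bad)) {
          stop(sprintf("non-numeric cell in continuous column '%s' at row %d",
                       nm, bad[1L]))
        }
        df[[nm]] <- conv
      }
    } else if (specs$vtype[i] == "categorical") {
      df[[nm]] <- as.character(df[[nm]])
      lv <- sort(unique(df[[nm]][!is.na(df[[nm]])]))
      if (length(lv) < 2L) {
        stop(sprintf("categorical column '%s' has fewer than 2 observed levels", nm))
      }
      levels[[nm]] <- lv
    } else {
      stop("vtype must be 'continuous' or 'categorical': ", specs$vtype[i])
    }
  }
  structure(
    list(df = df, specs = specs, levels = levels, n_samples = nrow(df)),
    class = "mindnet_data"
  )
}

#' Read a data table and its variable specification from disk
#'
#' The table is CSV or TSV with a header row (delimiter auto-detected from
#' the header line); the spec file is TSV/CSV with columns `name`, `vtype`
#' and `contextual` (0/1 or TRUE/FALSE).  Empty cells and the string `"NA"`
#' are treated as missing.
#'
#' @param path table file.
#' @param spec_path variable-specification file.
#' @return a [mindnet_data] object.
#' @export
read_table <- function(path, spec_path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  ssep <- detect_sep(spec_path)
  sp <- utils::read.table(spec_path, header = TRUE, sep = ssep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(sp) <- tolower(names(sp))
  if (!"contextual" %in% names(sp) && "is_contextual" %in% names(sp)) {
    sp$contextual <- sp$is_contextual
  }
  stopifnot(all(c("name", "vtype") %in% names(sp)))
  specs <- data.frame(
    name = as.character(sp$name),
    vtype = as.character(sp$vtype),
    is_contextual = as.logical(as.integer(as.logical(sp$contextual %||% FALSE)) == 1L),
    stringsAsFactors = FALSE
  )
  specs$is_contextual[is.na(specs$is_contextual)] <- FALSE
  mindnet_data(df, specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' @export
print.mindnet_data <- function(x, ...) {
  cat(sprintf("mindnet_data: %d samples x %d variables (%d continuous, %d categorical, %d contextual)\n",
              x$n_samples, nrow(x$specs),
              sum(x$specs$vtype == "continuous"),
              sum(x$specs$vtype == "categorical"),
              sum(x$specs$is_contextual)))
  invisible(x)
}

# complete cases over exactly the named variables
complete_rows <- function(data, vars) {
  sub <- data$df[vars]
  sub[stats::complete.cases(sub), , drop = FALSE]
}

vtype_of <- function(data, vars) {
  out <- as.list(data$specs$vtype[match(vars, data$specs$name)])
  names(out) <- vars
  out
}

var_names <- function(data) data$specs$name

is_contextual <- function(data, var) {
  data$specs$is_contextual[match(var, data$specs$name)]
}
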