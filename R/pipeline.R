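# The declarative pipeline surface: a key=value option-file language with
# nested Name(arg=value, arg=(a,b,c)) filter invocations, a filter
# registry with typed signatures, the execution engine and the CLI.
#
# Grammar (informal):
#   file        := line*
#   line        := comment | assignment | blank
#   comment     := '#' ...                   (also allowed after a value)
#   assignment  := key '=' value             (backslash continues a line)
#   value       := scalar | invocation-list
#   invocation  := Name | Name '(' arg (',' arg)* ')'
#   arg         := key '=' (scalar | '(' item (',' item)* ')')
# Scalars are typed against the filter signature: int, real, flag (yes/no),
# string, or list.

# ---- tokenizing helpers ---------------------------------------------------

# Split on top-level commas (ignoring commas inside parentheses).
split_top_level <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  parts <- character(0)
  cur <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("option syntax error: unbalanced ')' in: ", text)
    }
    if (ch == "," && depth == 0L) {
      parts <- c(parts, paste(cur, collapse = ""))
      cur <- character(0)
    } else cur <- c(cur, ch)
  }
  if (depth != 0L) stop("option syntax error: unbalanced '(' in: ", text)
  c(parts, paste(cur, collapse = ""))
}

# Parse one Name(arg=value, ...) invocation into list(name, args).
parse_invocation <- function(text) {
  text <- trimws(text)
  m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*(\\((.*)\\))?$", text)[[1L]]
  if (m[1] < 0L) stop("option syntax error: bad filter invocation: ", text)
  parts <- regmatches(text, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*(\\((.*)\\))?$",
                                    text))[[1L]]
  name <- parts[2]
  argtext <- parts[4]
  args <- list()
  if (!is.na(argtext) && nzchar(trimws(argtext))) {
    for (piece in split_top_level(argtext)) {
      piece <- trimws(piece)
      eq <- regexpr("=", piece, fixed = TRUE)
      if (eq < 0L)
        stop("option syntax error: argument without '=' in ", name, ": ", piece)
      key <- trimws(substr(piece, 1L, eq - 1L))
      val <- trimws(substr(piece, eq + 1L, nchar(piece)))
      if (startsWith(val, "(")) {
        if (!endsWith(val, ")"))
          stop("option syntax error: unterminated list for ", key)
        inner <- substr(val, 2L, nchar(val) - 1L)
        val <- trimws(split_top_level(inner))
      }
      args[[key]] <- val
    }
  }
  list(name = name, args = args)
}

#' Parse an option file into a pipeline specification
#'
#' Lines have the form `key=value`; `#` starts a comment, a trailing
#' backslash continues the line. Recognized keys are `input.file`,
#' `input.format` (`Maf` or `Fasta`), `input.compression` (`none`, `gzip`,
#' `bzip2`, `zip`, `auto`), `input.species` (Fasta import) and
#' `maf.filter`, a comma-separated list of filter invocations
#' `Name(arg=value, arg=(a,b,c), ...)`. Unknown top-level keys produce a
#' warning; unknown filter names or arguments are errors (checked against
#' the registry, see [list_filters()]). `overrides` (e.g. command-line
#' `key=value` arguments) replace file entries.
#'
#' @param text option-file content as a character vector of lines, or a
#'   file path when `is_path = TRUE`.
#' @param is_path treat `text` as a path.
#' @param overrides named character vector of key overrides.
#' @return an object of class `pipeline_spec` with fields `input` and
#'   `filters`.
#' @export
parse_options <- function(text, is_path = FALSE, overrides = character(0)) {
  lines <- if (is_path) readLines(text, warn = FALSE) else text
  # strip comments, join continuations
  lines <- sub("#.*$", "", lines)
  joined <- character(0)
  acc <- ""
  for (ln in lines) {
    if (grepl("\\\\\\s*$", ln)) {
      acc <- paste0(acc, sub("\\\\\\s*$", "", ln))
    } else {
      joined <- c(joined, paste0(acc, ln))
      acc <- ""
    }
  }
  if (nzchar(acc)) joined <- c(joined, acc)
  joined <- trimws(joined)
  joined <- joined[nzchar(joined)]
  kv <- list()
  for (ln in joined) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) stop("option syntax error: line without '=': ", ln)
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    kv[[key]] <- val
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]

  known <- c("input.file", "input.format", "input.compression",
             "input.species", "maf.filter")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown option key(s): ", paste(unknown, collapse = ", "))

  input <- list(
    file = kv[["input.file"]],
    format = tolower(kv[["input.format"]] %||% "maf"),
    compression = tolower(kv[["input.compression"]] %||% "auto"),
    species = kv[["input.species"]])
  if (!input$format %in% c("maf", "fasta"))
    stop("unsupported input.format: ", input$format)

  filters <- list()
  if (!is.null(kv[["maf.filter"]]) && nzchar(kv[["maf.filter"]])) {
    for (piece in split_top_level(kv[["maf.filter"]])) {
      piece <- trimws(piece)
      if (!nzchar(piece)) next
      filters[[length(filters) + 1L]] <- parse_invocation(piece)
    }
  }
  spec <- structure(list(input = input, filters = filters),
                    class = "pipeline_spec")
  validate_pipeline(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a pipeline specification back to option-file text
#'
#' Inverse of [parse_options()]: `parse_options(render_options(spec))`
#' reproduces `spec`.
#'
#' @param spec a `pipeline_spec`.
#' @return character vector of option-file lines.
#' @export
render_options <- function(spec) {
  render_val <- function(v)
    if (length(v) > 1L) paste0("(", paste(v, collapse = ","), ")") else v
  lines <- c(
    if (!is.null(spec$input$file)) paste0("input.file=", spec$input$file),
    paste0("input.format=", spec$input$format),
    paste0("input.compression=", spec$input$compression),
    if (!is.null(spec$input$species))
      paste0("input.species=", spec$input$species))
  if (length(spec$filters) > 0L) {
    invs <- vapply(spec$filters, function(f) {
      if (length(f$args) == 0L) return(f$name)
      argtxt <- paste(vapply(names(f$args), function(k)
        paste0(k, "=", render_val(f$args[[k]])), character(1)),
        collapse = ", ")
      paste0(f$name, "(", argtxt, ")")
    }, character(1))
    lines <- c(lines, paste0("maf.filter=", paste(invs, collapse = ", ")))
  }
  lines
}

# ---- typed argument binding ----------------------------------------------

convert_arg <- function(value, type, filter, key) {
  bad <- function(what) stop("filter ", filter, ": argument '", key,
                             "' expects ", what, ", got '",
                             paste(value, collapse = ","), "'")
  switch(type,
    int = {
      v <- suppressWarnings(as.integer(value))
      if (length(v) != 1L || is.na(v)) bad("an integer")
      v
    },
    real = {
      v <- suppressWarnings(as.numeric(value))
      if (length(v) != 1L || is.na(v)) bad("a number")
      v
    },
    flag = {
      if (!length(value) == 1L || !tolower(value) %in% c("yes", "no", "true", "false"))
        bad("yes/no")
      tolower(value) %in% c("yes", "true")
    },
    string = {
      if (length(value) != 1L) bad("a string")
      value
    },
    list = as.character(value),
    stop("internal: unknown arg type ", type))
}

arg_spec <- function(type, default = NULL, required = FALSE)
  list(type = type, default = default, required = required)

# ---- the filter registry --------------------------------------------------

# Each entry: list(args = named list of arg_spec, build = function(source,
# a, ctx) -> iterator). ctx carries sink registration for cleanup.
filter_registry <- function() {
  wclean_args <- function(extra) c(list(
    window_size = arg_spec("int", required = TRUE),
    window_step = arg_spec("int", required = TRUE),
    species = arg_spec("list", default = NULL),
    action = arg_spec("string", default = "remove")), extra)
  reg <- list(
    Subset = list(
      args = list(species = arg_spec("list", required = TRUE),
                  strict = arg_spec("flag", FALSE),
                  keep = arg_spec("flag", FALSE),
                  remove_duplicates = arg_spec("flag", FALSE),
                  keep_first = arg_spec("flag", FALSE)),
      build = function(source, a, ctx)
        flt_subset(source, a$species, strict = a$strict,
                   keep_others = a$keep,
                   remove_duplicates = a$remove_duplicates,
                   keep_first = a$keep_first)),
    Merge = list(
      args = list(species = arg_spec("list", required = TRUE),
                  dist_max = arg_spec("int", 0L)),
      build = function(source, a, ctx)
        flt_merge(source, a$species, max_dist = a$dist_max)),
    Concatenate = list(
      args = list(minimum_size = arg_spec("int", required = TRUE)),
      build = function(source, a, ctx)
        flt_concatenate(source, a$minimum_size)),
    XFullGap = list(
      args = list(species = arg_spec("list", required = TRUE)),
      build = function(source, a, ctx)
        flt_remove_full_gap_columns(source, a$species)),
    FeatureFilter = list(
      args = list(file = arg_spec("string", required = TRUE),
                  format = arg_spec("string", "gff3"),
                  ref_species = arg_spec("string", required = TRUE),
                  feature_species = arg_spec("string", default = NULL)),
      build = function(source, a, ctx)
        flt_feature_filter(source,
          read_features(a$file, a$format, species = a$feature_species),
          a$ref_species)),
    ExtractFeature = list(
      args = list(file = arg_spec("string", required = TRUE),
                  format = arg_spec("string", "gff3"),
                  ref_species = arg_spec("string", required = TRUE),
                  feature_species = arg_spec("string", default = NULL),
                  complete = arg_spec("flag", FALSE)),
      build = function(source, a, ctx)
        flt_extract_features(source,
          read_features(a$file, a$format, species = a$feature_species),
          a$ref_species, complete_only = a$complete)),
    SelectChr = list(
      args = list(ref_species = arg_spec("string", required = TRUE),
                  chromosome = arg_spec("string", required = TRUE)),
      build = function(source, a, ctx)
        flt_select_chromosome(source, a$ref_species, a$chromosome)),
    MinBlockLength = list(
      args = list(min_length = arg_spec("int", required = TRUE)),
      build = function(source, a, ctx)
        flt_min_block_length(source, a$min_length)),
    MinBlockSize = list(
      args = list(min_size = arg_spec("int", required = TRUE)),
      build = function(source, a, ctx)
        flt_min_block_size(source, a$min_size)),
    AlnFilter = list(
      args = wclean_args(list(max_gap = arg_spec("int", required = TRUE))),
      build = function(source, a, ctx)
        flt_sliding_window_clean(source, a$window_size, a$window_step,
          "gap_count", list(max_gap = a$max_gap), a$species, a$action)),
    AlnFilter2 = list(
      args = wclean_args(list(max_events = arg_spec("int", required = TRUE))),
      build = function(source, a, ctx)
        flt_sliding_window_clean(source, a$window_size, a$window_step,
          "gap_events", list(max_events = a$max_events), a$species, a$action)),
    EntropyFilter = list(
      args = wclean_args(list(max_entropy = arg_spec("real", required = TRUE),
                              max_columns = arg_spec("int", required = TRUE))),
      build = function(source, a, ctx)
        flt_sliding_window_clean(source, a$window_size, a$window_step,
          "entropy", list(entropy_threshold = a$max_entropy,
                          max_columns = a$max_columns), a$species, a$action)),
    MaskFilter = list(
      args = wclean_args(list(max_masked = arg_spec("int", required = TRUE))),
      build = function(source, a, ctx)
        flt_sliding_window_clean(source, a$window_size, a$window_step,
          "mask_count", list(max_masked = a$max_masked), a$species, a$action)),
    QualityFilter = list(
      args = wclean_args(list(min_quality = arg_spec("real", required = TRUE))),
      build = function(source, a, ctx)
        flt_sliding_window_clean(source, a$window_size, a$window_step,
          "quality_mean", list(min_quality = a$min_quality), a$species,
          a$action)),
    WindowSplit = list(
      args = list(window_size = arg_spec("int", required = TRUE),
                  align = arg_spec("string", "left")),
      build = function(source, a, ctx)
        flt_window_split(source, a$window_size, a$align)),
    SequenceStatistics = list(
      args = list(statistics = arg_spec("list", required = TRUE),
                  ref_species = arg_spec("string", required = TRUE),
                  file = arg_spec("string", required = TRUE)),
      build = function(source, a, ctx) {
        stats <- lapply(a$statistics, function(s) {
          inv <- parse_invocation(s)
          list(name = inv$name, args = inv$args)
        })
        flt_sequence_statistics(source, stats, a$ref_species, a$file)
      }),
    DistanceEstimation = list(
      args = list(method = arg_spec("string", "kimura")),
      build = function(source, a, ctx)
        flt_distance_estimation(source, a$method)),
    DistanceBasedPhylogeny = list(
      args = list(method = arg_spec("string", "nj")),
      build = function(source, a, ctx)
        flt_distance_based_phylogeny(source, a$method)),
    NewOutgroup = list(
      args = list(outgroup = arg_spec("string", required = TRUE)),
      build = function(source, a, ctx)
        flt_new_outgroup(source, a$outgroup)),
    DropSpecies = list(
      args = list(species = arg_spec("list", required = TRUE)),
      build = function(source, a, ctx)
        flt_drop_species(source, a$species)),
    Output = list(
      args = list(file = arg_spec("string", required = TRUE),
                  compression = arg_spec("string", "auto")),
      build = function(source, a, ctx) {
        w <- maf_writer(a$file, a$compression)
        ctx$register_sink(w$close)
        iter_flatmap(source, function(b) { w$write_block(b); list(b) })
      }),
    OutputAlignments = list(
      args = list(file = arg_spec("string", required = TRUE),
                  format = arg_spec("string", "fasta"),
                  relaxed = arg_spec("flag", TRUE)),
      build = function(source, a, ctx) {
        ordinal <- 0L
        iter_flatmap(source, function(b) {
          ordinal <<- ordinal + 1L
          path <- if (grepl("%i", a$file, fixed = TRUE))
            gsub("%i", ordinal, a$file, fixed = TRUE) else a$file
          write_alignment(b, path, a$format, relaxed = a$relaxed)
          list(b)
        })
      }),
    OutputTrees = list(
      args = list(file = arg_spec("string", required = TRUE)),
      build = function(source, a, ctx) {
        con <- file(a$file, "w")
        ctx$register_sink(function() close(con))
        iter_flatmap(source, function(b) {
          if (!is.null(b$tree)) writeLines(ape::write.tree(b$tree), con)
          list(b)
        })
      }),
    VcfOutput = list(
      args = list(file = arg_spec("string", required = TRUE),
                  reference = arg_spec("string", required = TRUE),
                  genotypes = arg_spec("flag", FALSE)),
      build = function(source, a, ctx) {
        w <- vcf_writer(a$file, a$reference, a$genotypes)
        ctx$register_sink(w$close)
        iter_flatmap(source, function(b) { w$write_block(b); list(b) })
      })
  )
  reg
}

#' List registered pipeline filters and their signatures
#' @return data.frame with columns `filter` and `signature`.
#' @export
list_filters <- function() {
  reg <- filter_registry()
  sig <- vapply(names(reg), function(n) {
    argdefs <- reg[[n]]$args
    paste(vapply(names(argdefs), function(k) {
      a <- argdefs[[k]]
      paste0(k, ":", a$type, if (isTRUE(a$required)) "*" else "")
    }, character(1)), collapse = ", ")
  }, character(1))
  data.frame(filter = names(reg), signature = unname(sig),
             stringsAsFactors = FALSE)
}

# Internal: check filter names and argument names/types against the registry.
validate_pipeline <- function(spec) {
  reg <- filter_registry()
  for (f in spec$filters) {
    if (!f$name %in% names(reg))
      stop("unknown filter name: ", f$name)
    argdefs <- reg[[f$name]]$args
    unknown <- setdiff(names(f$args), names(argdefs))
    if (length(unknown) > 0L)
      stop("filter ", f$name, ": unknown argument(s): ",
           paste(unknown, collapse = ", "))
    for (k in names(argdefs)) {
      if (isTRUE(argdefs[[k]]$required) && is.null(f$args[[k]]))
        stop("filter ", f$name, ": missing required argument '", k, "'")
      if (!is.null(f$args[[k]]))
        convert_arg(f$args[[k]], argdefs[[k]]$type, f$name, k)
    }
  }
  invisible(spec)
}

# Internal: bind typed argument values with defaults filled in.
bind_args <- function(f, argdefs) {
  a <- list()
  for (k in names(argdefs)) {
    if (!is.null(f$args[[k]])) {
      a[[k]] <- convert_arg(f$args[[k]], argdefs[[k]]$type, f$name, k)
    } else {
      d <- argdefs[[k]]$default
      if (!is.null(d)) a[k] <- list(d)
    }
  }
  a
}

#' Execute a pipeline specification
#'
#' Composes the lazy chain source -> filter1 -> ... -> filterN, drains it
#' block by block (single pass, bounded memory) and closes all sinks. Any
#' filter error aborts with the offending block ordinal and filter name.
#'
#' @param spec a `pipeline_spec` from [parse_options()].
#' @param verbose print per-filter progress to stderr.
#' @return list with `blocks_read`, `blocks_out`, `per_filter` (named
#'   emitted-block counts) and `elapsed` seconds.
#' @export
run_pipeline <- function(spec, verbose = FALSE) {
  validate_pipeline(spec)
  reg <- filter_registry()
  sinks <- list()
  ctx <- list(register_sink = function(f) sinks[[length(sinks) + 1L]] <<- f)
  t0 <- proc.time()[["elapsed"]]

  source <- switch(spec$input$format,
    maf = read_maf(spec$input$file, spec$input$compression),
    fasta = read_fasta_as_blocks(spec$input$file,
                                 species = spec$input$species,
                                 compression = spec$input$compression))
  counted_in <- iter_counting(source)
  chain <- counted_in
  counters <- list()
  for (i in seq_along(spec$filters)) {
    # per-iteration scope: filter closures must capture this filter's own
    # bound arguments, not a promise onto a loop variable reassigned later
    built <- (function(f) {
      a <- bind_args(f, reg[[f$name]]$args)
      reg[[f$name]]$build(chain, a, ctx)
    })(spec$filters[[i]])
    chain <- iter_counting(built)
    counters[[i]] <- chain$count
  }
  out_count <- 0L
  ordinal <- 0L
  repeat {
    b <- tryCatch(iter_next(chain), error = function(e) {
      stop("pipeline aborted at block ", ordinal + 1L, ": ",
           conditionMessage(e), call. = FALSE)
    })
    if (is.null(b)) break
    ordinal <- ordinal + 1L
    out_count <- out_count + 1L
    if (verbose && ordinal %% 500L == 0L)
      message("INFO <pipeline>: ", ordinal, " blocks emitted")
  }
  iter_close(chain)
  for (cl in sinks) cl()
  per_filter <- if (length(spec$filters) > 0L)
    stats::setNames(vapply(counters, function(f) f(), integer(1)),
                    vapply(spec$filters, function(f) f$name, character(1)))
  else integer(0)
  list(blocks_read = counted_in$count(),
       blocks_out = out_count,
       per_filter = per_filter,
       elapsed = proc.time()[["elapsed"]] - t0)
}

#' Command-line entry point
#'
#' Usage: `mafstream param=<optionfile> [key=value ...] [--verbose]
#' [--version] [--list-filters]`. A bare first argument is accepted as the
#' option file. Command-line `key=value` pairs override file entries.
#' Returns (rather than calls) the exit status: 0 on success, 1 on error,
#' 2 on usage problems.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if ("--version" %in% argv) {
    cat("mafstream ", as.character(utils::packageVersion("mafstream")), "\n",
        sep = "")
    return(0L)
  }
  if ("--list-filters" %in% argv) {
    lf <- list_filters()
    for (i in seq_len(nrow(lf)))
      cat(sprintf("%-24s %s\n", lf$filter[i], lf$signature[i]))
    return(0L)
  }
  verbose <- "--verbose" %in% argv
  argv <- setdiff(argv, c("--verbose"))
  kvs <- grepl("=", argv, fixed = TRUE)
  bare <- argv[!kvs]
  overrides <- character(0)
  param_file <- NULL
  for (a in argv[kvs]) {
    eq <- regexpr("=", a, fixed = TRUE)
    key <- substr(a, 1L, eq - 1L)
    val <- substr(a, eq + 1L, nchar(a))
    if (key == "param") param_file <- val else overrides[key] <- val
  }
  if (is.null(param_file) && length(bare) >= 1L) param_file <- bare[1L]
  if (is.null(param_file)) {
    message("ERROR <cli>: no option file given (param=<file>)")
    return(2L)
  }
  if (!file.exists(param_file)) {
    message("ERROR <cli>: option file not found: ", param_file)
    return(2L)
  }
  status <- tryCatch({
    spec <- parse_options(param_file, is_path = TRUE, overrides = overrides)
    summary <- run_pipeline(spec, verbose = verbose)
    message(sprintf(
      "INFO <pipeline>: %d block(s) read, %d emitted in %.2fs",
      summary$blocks_read, summary$blocks_out, summary$elapsed))
    0L
  }, error = function(e) {
    message("ERROR <pipeline>: ", conditionMessage(e))
    1L
  })
  status
}
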