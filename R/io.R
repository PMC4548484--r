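#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the recording format the pipeline expects
#' (integer PCM, single channel, 16 bits per sample).  Samples are scaled to
#' `[-1, 1)` by `1/32768` of the signed integer value.  Stereo or non-PCM
#' encodings raise an unsupported-format error.  Files at a rate other than
#' `expected_rate` are accepted with a warning — no resampling is performed;
#' the frame geometry adapts through [frame_params()].
#'
#' @param path file path.
#' @param expected_rate rate in Hz that triggers a warning when not matched
#'   (`NULL` disables the check).
#' @return An utterance: list with `samples`, `sample_rate`, `id`, `label`.
#' @export
read_wav <- function(path, expected_rate = 8000) {
  if (!file.exists(path)) rlang::abort(paste("no such file:", path), class = "frcc_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    rlang::abort("not a RIFF/WAVE file", class = "frcc_unsupported_format")
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels     = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    rlang::abort("missing fmt or data chunk", class = "frcc_unsupported_format")
  }
  if (fmt$audio_format != 1) {
    rlang::abort(sprintf("unsupported WAV encoding (format tag %d, want PCM = 1)", fmt$audio_format),
                 class = "frcc_unsupported_format")
  }
  if (fmt$channels != 1) {
    rlang::abort(sprintf("unsupported channel count %d (mono required)", fmt$channels),
                 class = "frcc_unsupported_format")
  }
  if (fmt$bits != 16) {
    rlang::abort(sprintf("unsupported bit depth %d (16-bit required)", fmt$bits),
                 class = "frcc_unsupported_format")
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2, size = 2,
                  signed = TRUE, endian = "little")
  if (!is.null(expected_rate) && fmt$sample_rate != expected_rate) {
    rlang::warn(sprintf("sample rate %d Hz differs from the expected %d Hz; no resampling performed",
                        fmt$sample_rate, expected_rate))
  }
  list(samples = ints / 32768, sample_rate = fmt$sample_rate,
       id = sub("\\.wav$", "", basename(path), ignore.case = TRUE),
       label = NA_character_)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param x an utterance list (with `samples`, `sample_rate`) or a numeric
#'   vector in `[-1, 1)`.
#' @param path output file path.
#' @param sample_rate rate in Hz (ignored when `x` carries one).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 8000) {
  if (is.list(x)) {
    sample_rate <- x$sample_rate %||% sample_rate
    x <- x$samples
  }
  ints <- as.integer(round(pmax(pmin(as.numeric(x), 1 - 1 / 32768), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(ints) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                       # PCM
  writeBin(1L, con, size = 2, endian = "little")                       # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")                       # block align
  writeBin(16L, con, size = 2, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Write a corpus as WAV files plus a delimited manifest
#'
#' @param corpus a corpus tibble from [gen_corpus()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(list(corpus$samples, corpus$id, corpus$sample_rate),
               function(s, id, sr) write_wav(as.numeric(s), file.path(dir, paste0(id, ".wav")), sr))
  manifest <- corpus_manifest(corpus)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Write/read a per-frame feature table as delimited text
#'
#' One row per frame: utterance id, frame index, order, label and the
#' feature columns.
#'
#' @param features a `frcc_features` object or a list of them.
#' @param path output TSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_features <- function(features, path) {
  if (inherits(features, "frcc_features")) features <- list(features)
  tab <- dplyr::bind_rows(lapply(features, as_tibble))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Serialize a fitted LDA model as structured text
#'
#' @param model a `frcc_lda` object.
#' @param path output YAML path.
#' @param config_hash optional configuration hash recorded with the model.
#' @return `path`, invisibly.
#' @export
write_lda_model <- function(model, path, config_hash = NULL) {
  yaml::write_yaml(list(type = "frcc_lda", w = model$w, threshold = model$threshold,
                        mu1 = model$mu1, mu2 = model$mu2, labels = model$labels,
                        n = model$n, J = model$J, dims = model$dims,
                        config_hash = config_hash,
                        version = as.character(utils::packageVersion("frcc"))),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$type, "frcc_lda")) rlang::abort("not an LDA model file", class = "frcc_io_error")
  structure(list(w = as.numeric(y$w), threshold = y$threshold,
                 mu1 = as.numeric(y$mu1), mu2 = as.numeric(y$mu2),
                 labels = as.character(y$labels), n = as.integer(y$n),
                 J = y$J, dims = as.character(y$dims)),
            class = "frcc_lda", config_hash = y$config_hash)
}

#' Serialize an HMM (plus optional codebook) as structured text
#'
#' @param model a `frcc_hmm` object.
#' @param path output YAML path.
#' @param codebook optional [vq_fit()] codebook stored alongside.
#' @param config_hash optional configuration hash recorded with the model.
#' @return `path`, invisibly.
#' @export
write_hmm_model <- function(model, path, codebook = NULL, config_hash = NULL) {
  out <- list(type = "frcc_hmm", n_states = model$n_states,
              n_symbols = model$n_symbols,
              A = apply(model$A, 1, identity, simplify = FALSE),
              B = apply(model$B, 1, identity, simplify = FALSE),
              pi = model$pi, seed = attr(model, "seed"),
              config_hash = config_hash,
              version = as.character(utils::packageVersion("frcc")))
  if (!is.null(codebook)) {
    out$codebook <- apply(codebook$centroids, 1, identity, simplify = FALSE)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(y$type, "frcc_hmm")) rlang::abort("not an HMM model file", class = "frcc_io_error")
  model <- hmm_model(do.call(rbind, y$A), do.call(rbind, y$B), as.numeric(y$pi))
  attr(model, "seed") <- y$seed
  attr(model, "config_hash") <- y$config_hash
  if (!is.null(y$codebook)) {
    attr(model, "codebook") <- structure(
      list(centroids = do.call(rbind, lapply(y$codebook, as.numeric)),
           K = length(y$codebook)),
      class = "frcc_codebook")
  }
  model
}

#' Pipeline run configuration
#'
#' Bundles frame geometry, feature configuration, the order grid, classifier
#' choice and split settings into one round-trippable record.  The
#' configuration hash (MD5 of the canonical YAML rendering) names every run
#' artifact so outputs can be traced to their exact settings.
#'
#' @param params a [frame_params()].
#' @param config a [frcc_config()].
#' @param grid numeric vector of orders.
#' @param classifier `"lda"` or `"hmm"`.
#' @param fraction train fraction.
#' @param seed integer seed.
#' @param synth a [synth_config()] for the `synth` stage (optional).
#' @return A list of class `run_config`.
#' @export
run_config <- function(params = frame_params(), config = frcc_config(),
                       grid = seq(0.01, 0.99, by = 0.01) * pi,
                       classifier = c("lda", "hmm"), fraction = 0.30, seed = 1,
                       synth = synth_config()) {
  classifier <- match.arg(classifier)
  structure(list(params = unclass(params), config = unclass(config),
                 grid = as.numeric(grid), classifier = classifier,
                 fraction = fraction, seed = as.integer(seed),
                 synth = unclass(synth)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(x, path) {
  yaml::write_yaml(unclass(x), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rc <- run_config(
    params = do.call(frame_params, y$params[c("sample_rate", "frame_len", "hop",
                                              "window", "preemphasis")]),
    config = do.call(frcc_config, y$config),
    grid = as.numeric(y$grid), classifier = y$classifier,
    fraction = y$fraction, seed = y$seed,
    synth = do.call(synth_config, y$synth)
  )
  rc
}

#' @rdname run_config
#' @param x a `run_config`.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(x), tmp, precision = 15)
  unname(tools::md5sum(tmp))
}
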