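# small shared helpers

# run expr with a local, restored RNG state so generators and trainers are
# pure functions of (parameters, seed)
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# md5 of a canonical JSON rendering (used for config hashes / manifests)
.json_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(tf))
}
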