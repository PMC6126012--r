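# Shared fixtures: the toy model is deterministic, so build it once per run.
the_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_model()
    cache
  }
})
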