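.onLoad <- function(libname, pkgname) {
  if (is.null(.encoder_registry[["onehot"]]))
    register_encoder(encoder("onehot", encode_onehot, function(L) 20L * L))
}
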