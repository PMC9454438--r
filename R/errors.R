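# Classed conditions used across the package. Every error carries the
# umbrella class "hci_error" plus a specific class that tests match on.

abort_hci <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "hci_error"),
                      call = call))
}

warn_hci <- function(message, class) {
  warning(warningCondition(message, class = c(class, "hci_warning")))
}
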