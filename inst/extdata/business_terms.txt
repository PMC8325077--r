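llc
inc
corp
corporation
ltd
company
enterprises
warehouse
storefront
headquarters
holdings
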