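(((sativa:2.41,meridionalis:2.41):4.35,punctata:6.76):8.24,brachyantha:15.00);
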