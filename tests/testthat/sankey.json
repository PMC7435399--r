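{"donors":"don","acceptors":"acc","flows":[{"donor":"don","acceptor":"acc","per_donor_atom":0.0707}],"donor_per_atom":{"don":0.0707},"acceptor_per_atom":{"acc":0.0707},"donor_per_molecule":{"don":0.0707},"acceptor_per_molecule":{"acc":0.0707},"total":1.414}
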