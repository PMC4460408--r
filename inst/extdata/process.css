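/* Cosmetic stylesheet so a process XML reads pleasantly in a browser. */
process { display: block; font-family: sans-serif; margin: 1em; }
header { display: block; color: #555; margin-bottom: 0.5em; }
header:before { content: "Process header"; display: block; font-weight: bold; }
author:before { content: "Author: "; font-weight: bold; }
contact:before { content: " <"; }
contact:after { content: ">"; }
date:before { content: " ("; }
date:after { content: ")"; }
description { display: block; margin: 0.5em 0; font-style: italic; }
inputs:before { content: "Inputs"; display: block; font-weight: bold; margin-top: 0.5em; }
references:before { content: "References"; display: block; font-weight: bold; margin-top: 0.5em; }
outputs:before { content: "Outputs"; display: block; font-weight: bold; margin-top: 0.5em; }
file { display: block; margin-left: 1em; }
file:before { content: attr(id) " [" attr(format) ", " attr(quantity) "] "; font-weight: bold; }
file > comment { color: #777; }
steps:before { content: "Analysis steps"; display: block; font-weight: bold; margin-top: 0.5em; }
step { display: block; margin: 0.5em 0 0.5em 1em; }
step:before { content: "Step " attr(index) ": "; font-weight: bold; }
tool { font-weight: bold; }
version:before { content: " v"; }
command { display: block; font-family: monospace; background: #f4f4f4; padding: 0.2em; }
loop:before { content: "loop over: "; color: #06c; }
loop { display: block; }
switch:before { content: "switch " attr(name) ": True=" attr(true) " False=" attr(false); color: #063; }
switch { display: block; }
step > comment { display: block; color: #777; }
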