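software
hardware
interface
server
servers
network
networks
bandwidth
browser
browsers
login
password
database
databases
website
websites
webpage
internet
wifi
download
downloads
upload
uploads
programming
algorithm
algorithms
processor
firmware
router
hosting
javascript
html
backend
frontend
debug
megabytes
gigabytes
operating
windows
linux
android
iphone
laptop
desktop
keyboard
mouse
monitor
modem
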